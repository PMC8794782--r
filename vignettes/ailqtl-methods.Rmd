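---
title: "Methods: QTL mapping and candidate-gene prioritization in advanced intercross lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL mapping and candidate-gene prioritization in advanced intercross lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ailqtl)
```

# Scope and model

`ailqtl` analyses advanced intercross lines (AILs) built from two fully
inbred, nearly isogenic founder lines (called S1 and S2 throughout).
Because the founders are opposite-homozygous at every informative marker,
a genotype is coded as the number of S1 alleles (0 = S2/S2, 1 = HET,
2 = S1/S1), and all effect estimates are reported as class means together
with the contrasts Δ(S1−HET) and Δ(S1−S2). The statistical model of the
scan is deliberately simple:

* per marker, `trait ~ genotype factor (+ covariates)` against
  `trait ~ covariates`, compared by a nested-model F-test on the
  individuals complete for that marker; `LOD = -log10(p)`.

The genotype enters as an **unordered 3-level factor (2 df)** rather than
an additive dosage: the deliverable of such a study is a table of three
class means, and dominance at metabolic loci is common. An additive
(1 df) scan is available via `qtl_scan(..., additive = TRUE)` for users
who prefer the narrower alternative. No kinship or polygenic term is
fitted: in a deeply intermated AIL of modest size, family structure is
weak, and the intended workflow screens a subfamily label as an ordinary
covariate instead (`screen_covariates()`, inclusion at p < 0.05).

Missing genotypes are never imputed; each marker is fitted on its
complete cases. Markers with fewer than two observed genotype classes or
no residual degrees of freedom get a missing LOD and a log entry.

# Multiple testing: simpleM

Dense marker panels in a two-founder AIL are highly redundant, so plain
Bonferroni over all markers is far too conservative. `simple_m()`
estimates the effective number of independent tests: markers are cut, per
chromosome, into consecutive windows of at most `window` markers
(default 820); in each window the pairwise genotype correlation matrix is
eigendecomposed and the window contributes the smallest k whose top-k
eigenvalues explain at least `C` of the total variance. `C = 0.995` is
the method's published default and is left untouched. The genome-wide
threshold is then `-log10(alpha / Meff)`; alpha = 0.05 and 0.01 define
"significant" and "highly significant". With the canonical Meff = 849
these are 4.23 and 4.93 — printed as 4.2/4.9 at one decimal.

Numerical notes: correlations use pairwise-complete observations, which
can produce a slightly indefinite matrix; negative eigenvalues are
clamped to zero before the cumulative ratio. A constant marker inside a
window contributes zero correlation (with a warning) instead of
poisoning the decomposition.

# Support intervals

`lod_drop_interval()` takes the peak marker (ties resolve to the lower
position), grows the maximal contiguous run around it with
`LOD >= peak - drop` (default drop 1.5), and reports the interval from
the **first marker beyond the run on each side**, clamped at the
chromosome ends. Reporting flanking markers rather than the run itself is
the convention for support intervals quoted in physical coordinates: the
true boundary lies somewhere between the last marker inside and the first
marker outside the drop region.

# Selective genotyping and the two-stage scan

Discovery genotyping often covers only the phenotypic tails (here: the
union of the upper and lower standardized extremes of the selection
traits, collected round-robin across traits until the target count is
reached — `select_tails()`; the original selection rule of the emulated
study is unstated, so a standardized union-of-tails was chosen once and
kept). Effect sizes estimated on tails are inflated. `two_stage_scan()`
therefore (1) scans the selected subset and declares peaks at the
simpleM/Bonferroni threshold, and (2) refits every peak marker on **all**
animals (array plus targeted follow-up genotypes) for the reported LOD,
class means and variance explained. A peak marker absent from the
follow-up genotypes keeps its stage-1 estimates and is flagged
`unconfirmed`. The acceptance suite verifies on simulations that the
stage-2 refit reduces the absolute effect-size bias in ≥ 80% of
replicates.

Model validity is checked per reported marker by `nonparametric_check()`:
Shapiro–Wilk on the model residuals; if p < 0.05, a Kruskal–Wallis test
across genotype classes must fall below the marker's parametric alpha for
the marker to stay confirmed.

# Phenotype QC

* `remove_outliers()` masks single measurements deviating more than
  k = 4 SD from the trait mean. The rule is **single-pass** (mean and SD
  include the outlier) and per-measurement, not per-animal: iterating the
  rule or deleting whole animals are stronger interventions than the
  stated rule implies, and a single pass is reproducible by construction.
  A trait with SD 0 removes nothing.
* `compute_auc()` is the trapezoidal area of glucose over time (oGTT /
  ITT summaries), over the measured interval only.
* `correlation_matrix()` tests each trait with Shapiro–Wilk at
  alpha = 0.05 (the gate level is a package choice; only the
  Pearson-vs-Spearman split itself is prescribed) and uses Pearson iff
  both traits of a pair pass, Spearman otherwise, on pairwise-complete
  observations.

# Causal modeling

When one QTL underlies two traits, `fit_causal_models()` compares three
Gaussian decompositions of the joint likelihood of (T1, T2) given the
genotype Q, each the sum of two linear components:

| model | decomposition |
|---|---|
| independent | [T1 \| Q] + [T2 \| Q] |
| causal T1→T2 | [T1 \| Q] + [T2 \| T1] |
| reactive T2→T1 | [T2 \| Q] + [T1 \| T2] |

The three models are non-nested, so they are compared by AICc (the
small-sample Akaike criterion on the summed log-likelihood with the
summed parameter count). Two guards implement the "no model fits"
fallback: the winner must beat the runner-up by at least `gap` AICc units
(default 2.0 — the conventional "positive support" divide), and each of
the winner's components must pass a Shapiro–Wilk residual screen at
p ≥ 0.01. Otherwise the verdict is `undetermined`. Verdicts are invariant
to affine rescaling of either trait, and swapping the pair swaps
causal and reactive, which the tests assert. `classify_qtl_effects()`
turns verdicts into per-trait `direct`/`indirect` labels and reports
contradictions across pairs instead of resolving them.

The exact model equations of the study this design emulates were not
published at desk scale; the decomposition above is the standard triad
likelihood formulation, and both the criterion gap and the
goodness-of-fit level are exposed as parameters for anyone wishing to
match a different convention.

# Expression analysis

Intensities are log2-transformed and quantile-normalized **per tissue**
(`normalize_expression()`): the reference distribution is the row mean of
the column-sorted matrix, values are assigned by rank, and ties receive
the mean of their ranks' reference values. This makes per-sample value
multisets identical (asserted by test), and agrees with `limma`'s
implementation on tie-free data (used as an independent oracle in the
tests, not as the implementation). Differential expression is a
per-probe **Welch** t-test (the unequal-variance form is the safer
default when only "t-tests" is specified) with fold change defined as
the difference of group means on the log2 scale (S1 − S2), and BH
adjustment across probes within tissue; a gene is "differentially
expressed" if its adjusted p < 0.05 in at least one tissue.
`cluster_by_line()` reports whether average-linkage clustering on
`1 - cor` separates the two lines perfectly when cut into two clusters,
plus a cohesion score (mean within-line minus between-line correlation).

# Candidate-gene prioritization

`prioritize_candidates()` implements the decision tree: protein-coding
genes whose ±1000 bp padded span overlaps the QTL interval (1-based
inclusive; padded abutment counts), removal of genes without any variant
between the lines, collapse of each gene's annotations to category flags,
and scoring. Default points: stop gain/loss 3; missense in a functional
domain 3; SIFT deleterious 3 / tolerated 1 (taken from the most severe
missense — deleterious dominates); promoter or splice site 3; UTR,
enhancer, CTCF site 1 each; DE in ≥ 1 tissue 2; KEGG membership 1.

**Counting mode.** The default is `per_category`: each category counts
once regardless of how many qualifying variants a gene carries. This is
the only mode that jointly reproduces all eight published scores of the
regression fixture shipped in `inst/extdata/candidate_gene_flags.tsv`
(e.g. a gene with two promoter SNPs earns the promoter points once);
`per_variant` counting is retained behind `scoring_scheme(mode =
"per_variant")` for users whose reading of the tree is additive per
variant. The fixture's KEGG flags are reconstructed (the original
per-gene pathway list is not public): they are the unique assignment
consistent with the published scores under category-once scoring.
Ranking is score-descending with a deterministic alphabetical tie-break,
and the top two genes per QTL are flagged.

# The synthetic-data generator

`simulate_ail_genotypes()` drops gametes through the pedigree: the F1 of
two opposite-homozygous founders is followed by `n_generations` rounds of
random mating with balanced pair contributions (each random pair leaves
an equal number of offspring — the RandoMate-style scheme, which roughly
doubles the effective population size and halves drift). Each meiosis
draws `Poisson(length/1e8 × rate)` crossovers per chromosome, placed
uniformly with no interference. The default rate, 0.5 crossovers per
100 Mb per meiosis, matches the mouse genome-wide average of roughly
0.5 cM/Mb; only physical positions are modeled because AIL studies of
this kind publish bp coordinates, not genetic maps.

What the generator emulates: two-founder mosaic genomes, LD decaying
with distance and generations, allele frequencies drifting around 0.5,
Hardy–Weinberg-compatible class frequencies, selective genotyping of
phenotypic tails, planted additive/dominance effects, mediated
(causal-chain) effects built in topological order of the mediation graph,
a small-integer litter-size covariate (range 4–12), and group-structured
expression with a planted log2 shift. What it does **not** emulate:
genotyping error, sex chromosomes and mitochondria (all chromosomes are
treated as autosomes — the emulated study used males and reported
autosomal QTL), crossover interference, real founder haplotype structure,
selection during breeding, and array-specific artifacts. Passing tests
therefore demonstrate the statistical machinery under a clean generative
model, not robustness to those real-data complications.

A note on drift: with ~1,000 individuals and ten generations, the
Wright–Fisher drift standard deviation of the allele frequency
(≈ `sqrt(pq(1-(1-1/(2Ne))^g))` with Ne ≈ 2N) is of the same order as the
final binomial sampling error, so the generator's allele-frequency test
uses the drift-aware bound rather than a drift-free one.

# Numerical choices and degenerate inputs

* p-values are floored at 1e-300; LOD is capped at 300 (configurable) so
  perfect fits are reported finitely.
* The no-covariate scan is computed by a vectorized one-way ANOVA over
  all markers (group sums via matrix products), verified in tests against
  per-marker `lm()` fits including under missing genotypes; covariate
  scans fall back to per-marker nested `lm()` fits.
* Degenerate causal fits (an exact trait copy gives two perfect
  components with infinite likelihood) compare as an exact tie and fall
  through to `undetermined`.
* Constant traits yield NA correlations; constant covariates are excluded
  with a warning; a single-sample tissue is log2-transformed only.
* All simulation entry points take explicit integer seeds and are
  bit-reproducible; the pipeline derives stage seeds from one root seed.

# Problem sizes used by the test suite

The property-based checks run at deliberately moderate sizes chosen to
exercise the study design while keeping the suite quick: 20 replicate
scans of a 397-animal AIL over five 100-Mb chromosomes with 1,000 markers
for QTL localization (peak within 5 Mb in ≥ 90%), 100 phenotype
replicates for 1.5-LOD-drop coverage (≥ 90%), 50 replicates per causal
architecture (≥ 80% recovery), and 25 replicates for the
selective-genotyping bias reduction (≥ 80%). These rates are properties
of the generative settings above, not of any external dataset.

# Known limitations

* Single-QTL, single-marker models only: no multi-QTL or epistasis scans,
  no X-dosage model.
* Causal modeling is pairwise and assumes Gaussian errors and no
  measurement-error/latent confounding; with strong non-normality the
  fit screen will (by design) push verdicts to `undetermined`.
* The prioritization tree takes annotations, DE calls and KEGG flags as
  inputs; it does not run VEP/SIFT or query pathway databases.
* Quantile normalization assumes comparable global distributions across
  samples within a tissue; strong global shifts between lines are
  normalized away by construction.
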