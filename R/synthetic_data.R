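#' Describe an advanced intercross line design
#'
#' An AIL starts from a cross between two fully inbred, opposite-homozygous
#' founder lines (S1 male x S2 female); the F1 is followed by
#' `n_generations` rounds of random intermating. Only informative markers
#' (those differing between the founders) are simulated, mirroring a
#' nearly-isogenic founder pair where a few thousand SNPs segregate.
#'
#' @param n_individuals number of individuals in every generation,
#'   including the final sampled one (>= 2).
#' @param n_generations intermating generations after the F1 (0 returns the
#'   F1 itself; generation 10 of the emulated study corresponds to 9).
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param marker_positions named list (same names) of strictly increasing
#'   1-based bp positions.
#' @param recombination_rate expected crossovers per 100 Mb per meiosis
#'   (default 0.5, mouse-like ~0.5 cM/Mb).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list of class `ail_design`.
#' @export
ail_design <- function(n_individuals, n_generations = 9, chromosomes,
                       marker_positions, recombination_rate = 0.5,
                       seed = 1L) {
  assert_scalar_number(n_individuals, "n_individuals", lower = 2)
  assert_scalar_number(n_generations, "n_generations", lower = 0)
  assert_scalar_number(recombination_rate, "recombination_rate", lower = 0)
  stopifnot(is.numeric(chromosomes), !is.null(names(chromosomes)),
            all(chromosomes > 0))
  stopifnot(is.list(marker_positions),
            setequal(names(marker_positions), names(chromosomes)))
  for (ch in names(marker_positions)) {
    p <- marker_positions[[ch]]
    if (length(p) < 1 || any(diff(p) <= 0))
      stopf("marker positions on %s must be strictly increasing", ch)
    if (any(p < 1) || any(p > chromosomes[[ch]]))
      stopf("marker positions on %s outside [1, length]", ch)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_generations = as.integer(n_generations),
                 chromosomes = chromosomes,
                 marker_positions = marker_positions[names(chromosomes)],
                 recombination_rate = recombination_rate,
                 seed = as.integer(seed)),
            class = "ail_design")
}

#' Evenly spaced marker map helper
#'
#' @param chromosomes named numeric vector of lengths (bp).
#' @param n_markers markers per chromosome.
#' @return named list of positions usable in [ail_design()].
#' @export
even_marker_map <- function(chromosomes, n_markers) {
  lapply(chromosomes, function(L) round(seq(1, L, length.out = n_markers)))
}

# one gamete from a parent's two haplotypes on one chromosome.
# hap_a/hap_b: founder-origin vectors (1 = S1, 0 = S2) at `pos`; L in bp.
.gamete <- function(hap_a, hap_b, pos, L, rate) {
  k <- rpois(1L, L / 1e8 * rate)
  start <- sample.int(2L, 1L) - 1L          # which haplotype leads
  if (k == 0L) return(if (start == 0L) hap_a else hap_b)
  xo <- sort(runif(k, 0, L))
  seg <- findInterval(pos, xo)
  use_a <- (seg + start) %% 2L == 0L
  ifelse(use_a, hap_a, hap_b)
}

#' Simulate AIL genotypes by gamete dropping
#'
#' Founders are fully inbred and opposite-homozygous at every marker. Each
#' meiosis draws a Poisson number of crossovers per chromosome
#' (`length/1e8 * recombination_rate`), places them uniformly (no
#' interference), and builds the transmitted haplotype as the resulting
#' founder-origin mosaic. Each intermating generation keeps the population
#' at `n_individuals`, pairing individuals at random and giving every pair
#' a balanced number of offspring (RandoMate-style rotation, which roughly
#' doubles the effective population size relative to free random union of
#' gametes and so halves drift).
#'
#' @param design an [ail_design()].
#' @return A [geno_matrix()] (codes count S1 alleles: 0/1/2).
#' @export
simulate_ail_genotypes <- function(design) {
  stopifnot(inherits(design, "ail_design"))
  set.seed(design$seed)
  N <- design$n_individuals
  chrs <- names(design$chromosomes)
  rate <- design$recombination_rate
  # F1: maternal haplotype all S1 (1), paternal all S2 (0)
  hapA <- lapply(chrs, function(ch)
    matrix(1L, N, length(design$marker_positions[[ch]])))
  hapB <- lapply(chrs, function(ch)
    matrix(0L, N, length(design$marker_positions[[ch]])))
  names(hapA) <- names(hapB) <- chrs
  g <- 0L
  while (g < design$n_generations) {
    npair <- N %/% 2L
    perm <- sample.int(N)
    mothers <- perm[seq_len(npair)]
    fathers <- perm[npair + seq_len(npair)]
    pair_of <- sample(rep_len(seq_len(npair), N))   # balanced contributions
    newA <- hapA; newB <- hapB
    for (ch in chrs) {
      pos <- design$marker_positions[[ch]]
      L <- design$chromosomes[[ch]]
      A <- hapA[[ch]]; B <- hapB[[ch]]
      nA <- newA[[ch]]; nB <- newB[[ch]]
      for (i in seq_len(N)) {
        m <- mothers[pair_of[i]]; f <- fathers[pair_of[i]]
        nA[i, ] <- .gamete(A[m, ], B[m, ], pos, L, rate)
        nB[i, ] <- .gamete(A[f, ], B[f, ], pos, L, rate)
      }
      newA[[ch]] <- nA; newB[[ch]] <- nB
    }
    hapA <- newA; hapB <- newB
    g <- g + 1L
  }
  map <- do.call(rbind, lapply(chrs, function(ch)
    data.frame(marker = sprintf("%s_%d", ch, design$marker_positions[[ch]]),
               chr = ch, pos = design$marker_positions[[ch]])))
  geno <- do.call(rbind, lapply(chrs, function(ch) t(hapA[[ch]] + hapB[[ch]])))
  colnames(geno) <- sprintf("AIL%04d", seq_len(N))
  geno_matrix(map, geno)
}

# ---------------------------------------------------------------------------
# phenotypes with planted QTL architecture

#' Specify a planted QTL effect
#'
#' Each spec adds, to `target_trait`, `additive_effect` per S1-allele copy
#' plus `dominance_effect` for heterozygotes at `marker`, an optional
#' mediated contribution `slope * mediator` (a causal-chain effect through
#' another trait), and Gaussian noise with SD `noise_sd`. A spec with
#' `marker = NA` contributes only mediation and noise.
#'
#' @param target_trait trait name.
#' @param marker marker id in the genotype matrix, or `NA`.
#' @param additive_effect trait units per S1-allele copy.
#' @param dominance_effect trait units added to heterozygotes.
#' @param mediator,slope optional mediating trait and its slope.
#' @param noise_sd residual SD (>= 0).
#' @return list of class `qtl_spec`.
#' @export
qtl_spec <- function(target_trait, marker = NA_character_,
                     additive_effect = 0, dominance_effect = 0,
                     mediator = NULL, slope = 0, noise_sd = 1) {
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(mediator) && identical(mediator, target_trait))
    stopf("mediator and target_trait must differ (%s)", target_trait)
  structure(list(target_trait = target_trait, marker = marker,
                 additive_effect = additive_effect,
                 dominance_effect = dominance_effect,
                 mediator = mediator, slope = slope, noise_sd = noise_sd),
            class = "qtl_spec")
}

# topological order of traits under mediator -> target edges
.trait_order <- function(specs) {
  traits <- unique(c(vapply(specs, `[[`, "", "target_trait"),
                     unlist(lapply(specs, `[[`, "mediator"))))
  deps <- lapply(traits, function(t)
    unlist(lapply(specs, function(s)
      if (identical(s$target_trait, t) && !is.null(s$mediator)) s$mediator)))
  names(deps) <- traits
  out <- character(0)
  repeat {
    ready <- traits[!traits %in% out &
                      vapply(traits, function(t) all(deps[[t]] %in% out), TRUE)]
    if (!length(ready)) {
      if (length(out) < length(traits))
        stopf("cyclic mediation graph among traits: %s",
              paste(setdiff(traits, out), collapse = ", "))
      break
    }
    out <- c(out, ready)
    if (length(out) == length(traits)) break
  }
  out
}

#' Simulate phenotypes with planted direct and mediated QTL effects
#'
#' Traits are built in topological order of the mediation graph: baseline +
#' genotype effects + mediated contributions + independent Gaussian noise.
#' An optional litter-size covariate (small integers, default range 4-12)
#' is drawn per individual and added with the given effect to the named
#' traits, emulating a maternal-environment covariate on e.g. liver weight.
#'
#' @param genotypes a [geno_matrix()].
#' @param qtl_specs list of [qtl_spec()] objects.
#' @param covariate_spec optional
#'   `list(traits = <names>, effect = <units per pup>, range = 4:12)`.
#' @param baselines named numeric of trait baselines (default 0).
#' @param n_subfamilies subfamily labels to assign at random (pedigree
#'   grouping placeholder).
#' @param seed integer seed.
#' @return phenotype data.frame (`id`, traits, `litter_size`, `subfamily`,
#'   `line`, `genotyped_by`).
#' @export
simulate_phenotypes <- function(genotypes, qtl_specs, covariate_spec = NULL,
                                baselines = NULL, n_subfamilies = 10,
                                seed = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  stopifnot(all(vapply(qtl_specs, inherits, TRUE, "qtl_spec")))
  for (s in qtl_specs)
    if (!is.na(s$marker) && !s$marker %in% genotypes$map$marker)
      stopf("unknown marker in qtl_spec: %s", s$marker)
  set.seed(seed)
  ids <- colnames(genotypes$geno)
  n <- length(ids)
  traits <- .trait_order(qtl_specs)
  vals <- matrix(0, n, length(traits), dimnames = list(ids, traits))
  for (t in traits) vals[, t] <- baselines[[t]] %||% 0
  litter <- sample(covariate_spec$range %||% 4:12, n, replace = TRUE)
  for (t in traits) {
    for (s in qtl_specs) {
      if (!identical(s$target_trait, t)) next
      if (!is.na(s$marker)) {
        code <- genotypes$geno[s$marker, ids]
        vals[, t] <- vals[, t] + s$additive_effect * code +
          s$dominance_effect * (code == 1L)
      }
      if (!is.null(s$mediator))
        vals[, t] <- vals[, t] + s$slope * vals[, s$mediator]
      if (s$noise_sd > 0)
        vals[, t] <- vals[, t] + rnorm(n, 0, s$noise_sd)
    }
    if (!is.null(covariate_spec) && t %in% covariate_spec$traits)
      vals[, t] <- vals[, t] + covariate_spec$effect * litter
  }
  out <- data.frame(id = ids, as.data.frame(vals), check.names = FALSE)
  out$litter_size <- litter
  out$subfamily <- sprintf("fam%02d", sample.int(n_subfamilies, n, replace = TRUE))
  out$line <- NA_character_
  out$genotyped_by <- "array"
  rownames(out) <- NULL
  out
}

#' Select phenotypic-tail individuals for selective genotyping
#'
#' Ranks individuals within each trait by standardized score (z) and
#' collects ids round-robin from the four streams (trait 1 upper tail,
#' trait 1 lower tail, trait 2 upper, ...) until `n_select` distinct ids
#' are gathered. Deterministic; ties broken by id order.
#'
#' @param phenotypes phenotype data.frame with `id`.
#' @param traits trait names used for selection.
#' @param n_select number of individuals to pick (<= n).
#' @return character vector of selected ids (in input-id order).
#' @export
select_tails <- function(phenotypes, traits, n_select) {
  if (!length(traits)) stopf("at least one selection trait is required")
  stopifnot(all(traits %in% names(phenotypes)))
  n <- nrow(phenotypes)
  if (n_select > n) stopf("n_select (%d) exceeds population size (%d)", n_select, n)
  ids <- as.character(phenotypes$id)
  streams <- list()
  for (tr in traits) {
    x <- phenotypes[[tr]]
    z <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
    ok <- which(!is.na(z))
    up <- ok[order(-z[ok], ids[ok])]
    lo <- ok[order(z[ok], ids[ok])]
    streams <- c(streams, list(up), list(lo))
  }
  chosen <- integer(0)
  ptr <- rep(1L, length(streams))
  while (length(chosen) < n_select) {
    advanced <- FALSE
    for (k in seq_along(streams)) {
      s <- streams[[k]]
      while (ptr[k] <= length(s) && s[ptr[k]] %in% chosen) ptr[k] <- ptr[k] + 1L
      if (ptr[k] <= length(s)) {
        chosen <- c(chosen, s[ptr[k]])
        ptr[k] <- ptr[k] + 1L
        advanced <- TRUE
        if (length(chosen) >= n_select) break
      }
    }
    if (!advanced) break
  }
  ids[sort(chosen)]
}

# ---------------------------------------------------------------------------
# group-structured expression data

#' Describe a two-line expression experiment
#'
#' @param n_probes number of probes.
#' @param n_samples_per_line samples per line label (>= 2).
#' @param de_fraction fraction of probes with a planted mean shift.
#' @param effect_size_log2 planted shift (line S1 minus S2, log2 units).
#' @param noise_sd residual SD in log2 units.
#' @param baseline_log2 mean log2 intensity of unshifted probes.
#' @param tissue tissue label.
#' @param seed integer seed.
#' @return list of class `expression_design`.
#' @export
expression_design <- function(n_probes = 1000, n_samples_per_line = 8,
                              de_fraction = 0.1, effect_size_log2 = 1,
                              noise_sd = 0.3, baseline_log2 = 8,
                              tissue = "gonadal_adipose", seed = 1L) {
  assert_scalar_number(de_fraction, "de_fraction", lower = 0, upper = 1)
  assert_scalar_number(n_samples_per_line, "n_samples_per_line", lower = 2)
  structure(list(n_probes = as.integer(n_probes),
                 n_samples_per_line = as.integer(n_samples_per_line),
                 de_fraction = de_fraction,
                 effect_size_log2 = effect_size_log2,
                 noise_sd = noise_sd, baseline_log2 = baseline_log2,
                 tissue = tissue, seed = as.integer(seed)),
            class = "expression_design")
}

#' Simulate a group-structured expression matrix
#'
#' Intensities are generated on the log2 scale (probe-specific baselines
#' around `baseline_log2`, a planted shift on the first
#' `de_fraction * n_probes` probes for line S1, Gaussian noise) and
#' returned on the raw intensity scale (2^x), ready for [normalize_expression()].
#'
#' @param design an [expression_design()].
#' @return list: `x` an [expr_matrix()], `de_probes` the planted probe ids.
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "expression_design"))
  set.seed(design$seed)
  np <- design$n_probes; ns <- design$n_samples_per_line
  probe_ids <- sprintf("probe%05d", seq_len(np))
  base <- rnorm(np, design$baseline_log2, 1.5)
  n_de <- round(design$de_fraction * np)
  shift <- c(rep(design$effect_size_log2, n_de), rep(0, np - n_de))
  mk <- function(line, shifted) {
    mu <- base + if (shifted) shift else 0
    matrix(rnorm(np * ns, mu, design$noise_sd), np, ns)
  }
  vals <- cbind(mk("S1", TRUE), mk("S2", FALSE))
  samples <- data.frame(
    sample = c(sprintf("S1_%02d", seq_len(ns)), sprintf("S2_%02d", seq_len(ns))),
    line = rep(c("S1", "S2"), each = ns),
    tissue = design$tissue)
  probes <- data.frame(probe = probe_ids, gene = sub("probe", "gene", probe_ids))
  list(x = expr_matrix(2^vals, probes, samples, log2_scale = FALSE),
       de_probes = probe_ids[seq_len(n_de)])
}

# ---------------------------------------------------------------------------
# gene models and variant annotations (downstream-stage plumbing)

#' Simulate gene models tiled along the chromosomes of a map
#'
#' @param g a [geno_matrix()] whose chromosomes to tile.
#' @param genes_per_chr genes per chromosome.
#' @param gene_length gene span in bp.
#' @param seed integer seed.
#' @return gene model data.frame (`gene`, `name`, `chr`, `start`, `end`,
#'   `biotype`).
#' @export
simulate_gene_models <- function(g, genes_per_chr = 50, gene_length = 2e4,
                                 seed = 1L) {
  stopifnot(inherits(g, "geno_matrix"))
  set.seed(seed)
  chrs <- unique(g$map$chr)
  out <- do.call(rbind, lapply(seq_along(chrs), function(i) {
    ch <- chrs[i]
    L <- max(g$map$pos[g$map$chr == ch])
    start <- round(seq(1, max(1, L - gene_length), length.out = genes_per_chr))
    data.frame(gene = sprintf("ENSMUSG%s%03d", i, seq_len(genes_per_chr)),
               name = sprintf("Gene%s_%03d", ch, seq_len(genes_per_chr)),
               chr = ch, start = start,
               end = pmin(start + gene_length - 1, L),
               biotype = sample(c("protein_coding", "lncRNA"), genes_per_chr,
                                replace = TRUE, prob = c(0.85, 0.15)))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a variant annotation table over gene models
#'
#' A random subset of genes is made polymorphic; each receives 1-4 variants
#' with consequences drawn from the annotation vocabulary (missense
#' variants get SIFT classes and functional-domain flags).
#'
#' @param genes gene model data.frame.
#' @param polymorphic_fraction fraction of genes receiving variants.
#' @param seed integer seed.
#' @return validated annotation data.frame.
#' @export
simulate_variant_annotations <- function(genes, polymorphic_fraction = 0.3,
                                         seed = 1L) {
  set.seed(seed)
  poly <- genes[runif(nrow(genes)) < polymorphic_fraction, , drop = FALSE]
  rows <- list()
  vid <- 0L
  for (i in seq_len(nrow(poly))) {
    gn <- poly[i, ]
    for (j in seq_len(sample.int(4L, 1L))) {
      vid <- vid + 1L
      cons <- sample(c("missense", "promoter", "utr", "enhancer",
                       "ctcf_binding_site", "splice_site", "other"), 1L,
                     prob = c(0.25, 0.15, 0.2, 0.15, 0.1, 0.05, 0.1))
      miss <- cons == "missense"
      rows[[length(rows) + 1L]] <- data.frame(
        variant = sprintf("var%05d", vid), chr = gn$chr,
        pos = sample(seq(max(1, gn$start - 1000), gn$end + 1000), 1L),
        gene = gn$gene, consequence = cons,
        in_functional_domain = miss && runif(1) < 0.5,
        sift_class = if (miss) sample(c("deleterious", "tolerated"), 1L) else "none")
    }
  }
  if (!length(rows))
    return(validate_variant_annotations(
      data.frame(variant = character(), chr = character(), pos = numeric(),
                 gene = character(), consequence = character(),
                 in_functional_domain = logical(), sift_class = character())))
  validate_variant_annotations(do.call(rbind, rows))
}
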