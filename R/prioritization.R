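#' Candidate-gene scoring scheme
#'
#' Point values of the decision tree used to prioritize positional
#' candidate genes from variant annotation, expression and pathway
#' evidence. Defaults: stop gain/loss 3; missense in a functional protein
#' domain 3; SIFT-deleterious missense 3, SIFT-tolerated 1; non-coding
#' variant in a promoter or splice site 3; in a UTR, enhancer or CTCF
#' binding site 1 each; differential expression in at least one tissue 2;
#' membership of a relevant KEGG metabolic pathway 1.
#'
#' In `per_category` mode (default) each category is counted once no
#' matter how many qualifying variants a gene carries; `per_variant`
#' counts every qualifying variant.
#'
#' @param stop_gain_or_loss,missense_in_domain,sift_deleterious,sift_tolerated,promoter_or_splice,utr,enhancer,ctcf
#'   category points (>= 0).
#' @param de_any_tissue,kegg expression / pathway points.
#' @param mode `"per_category"` or `"per_variant"`.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(stop_gain_or_loss = 3, missense_in_domain = 3,
                           sift_deleterious = 3, sift_tolerated = 1,
                           promoter_or_splice = 3, utr = 1, enhancer = 1,
                           ctcf = 1, de_any_tissue = 2, kegg = 1,
                           mode = c("per_category", "per_variant")) {
  pts <- c(stop_gain_or_loss = stop_gain_or_loss,
           missense_in_domain = missense_in_domain,
           sift_deleterious = sift_deleterious,
           sift_tolerated = sift_tolerated,
           promoter_or_splice = promoter_or_splice,
           utr = utr, enhancer = enhancer, ctcf = ctcf,
           de_any_tissue = de_any_tissue, kegg = kegg)
  if (any(pts < 0)) stopf("all point values must be >= 0")
  structure(list(points = pts, mode = match.arg(mode)),
            class = "scoring_scheme")
}

#' Positional candidate genes of a QTL interval
#'
#' Protein-coding genes whose padded span `[start - pad, end + pad]`
#' overlaps the interval `[start, stop]` (1-based inclusive; padded
#' abutment counts as overlap). The pad captures proximal regulatory
#' regions such as promoters.
#'
#' @param interval one-row data.frame with `chr`, `start`, `stop`.
#' @param genes gene model data.frame (`gene`, `name`, `chr`, `start`,
#'   `end`, `biotype`).
#' @param pad bp added to each gene end (default 1000).
#' @return subset of `genes`.
#' @export
candidate_genes <- function(interval, genes, pad = 1000) {
  if (!nrow(genes)) stopf("empty gene table")
  stopifnot(all(c("chr", "start", "stop") %in% names(interval)))
  keep <- genes$biotype == "protein_coding" &
    genes$chr == interval$chr[1] &
    (genes$start - pad) <= interval$stop[1] &
    (genes$end + pad) >= interval$start[1]
  genes[keep, , drop = FALSE]
}

#' Drop genes monomorphic between the founder lines
#'
#' Keeps genes with at least one sequence variant in their padded span;
#' genes without any variant between the two lines carry no candidate
#' signal and are removed.
#'
#' @param genes gene model data.frame.
#' @param variants a variant annotation data.frame.
#' @param pad bp padding around each gene (default 1000).
#' @return subset of `genes`.
#' @export
polymorphic_filter <- function(genes, variants, pad = 1000) {
  if (!nrow(genes)) return(genes)
  keep <- vapply(seq_len(nrow(genes)), function(i) {
    gn <- genes[i, ]
    any(variants$chr == gn$chr &
          variants$pos >= gn$start - pad &
          variants$pos <= gn$end + pad)
  }, TRUE)
  genes[keep, , drop = FALSE]
}

#' Collapse one gene's variant annotations to category flags
#'
#' Sets each scoring-category flag when at least one qualifying variant
#' exists. `missense_in_domain` requires `in_functional_domain = TRUE`;
#' the SIFT flag is taken from the most severe missense variant
#' (deleterious dominates tolerated), so at most one of
#' `sift_deleterious` / `sift_tolerated` is set. Per-variant counts are
#' returned alongside for `per_variant` scoring.
#'
#' @param ann annotation rows of a single gene.
#' @return list: `flags` (named logical), `counts` (named integer).
#' @export
flags_from_annotations <- function(ann) {
  if (nrow(ann) && length(unique(ann$gene)) > 1)
    stopf("annotation rows span multiple genes: %s",
          paste(unique(ann$gene), collapse = ", "))
  cons <- ann$consequence
  miss <- cons == "missense"
  counts <- c(
    stop_gain_or_loss = sum(cons %in% c("stop_gain", "stop_loss")),
    missense_in_domain = sum(miss & ann$in_functional_domain),
    sift_deleterious = sum(miss & ann$sift_class == "deleterious"),
    sift_tolerated = sum(miss & ann$sift_class == "tolerated"),
    promoter_or_splice = sum(cons %in% c("promoter", "splice_site")),
    utr = sum(cons == "utr"),
    enhancer = sum(cons == "enhancer"),
    ctcf = sum(cons == "ctcf_binding_site"))
  flags <- counts > 0
  # severity dominance: one SIFT category, from the most severe missense
  if (flags["sift_deleterious"]) flags["sift_tolerated"] <- FALSE
  list(flags = flags, counts = counts)
}

#' Score one candidate gene
#'
#' Sums the decision-tree points: variant categories (once per category in
#' `per_category` mode, per qualifying variant in `per_variant` mode),
#' plus the differential-expression and KEGG points. Flags are validated
#' against the category invariants (a SIFT flag without any missense
#' category is inconsistent).
#'
#' @param flags named logical vector as returned by
#'   [flags_from_annotations()]`$flags`.
#' @param de_in_any_tissue logical.
#' @param kegg_relevant logical.
#' @param scheme a [scoring_scheme()].
#' @param counts per-category variant counts (required for `per_variant`
#'   mode).
#' @return integer total score.
#' @export
score_gene <- function(flags, de_in_any_tissue, kegg_relevant,
                       scheme = scoring_scheme(), counts = NULL) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  cats <- setdiff(names(scheme$points), c("de_any_tissue", "kegg"))
  if (!all(cats %in% names(flags)))
    stopf("missing category flags: %s",
          paste(setdiff(cats, names(flags)), collapse = ", "))
  flags <- flags[cats]
  if (flags["sift_deleterious"] && flags["sift_tolerated"])
    stopf("inconsistent flags: both SIFT categories set")
  if (scheme$mode == "per_variant") {
    if (is.null(counts)) stopf("per_variant mode requires `counts`")
    counts <- counts[cats]
    var_pts <- sum(scheme$points[cats] * counts)
  } else {
    var_pts <- sum(scheme$points[cats][flags])
  }
  total <- var_pts +
    scheme$points[["de_any_tissue"]] * isTRUE(de_in_any_tissue) +
    scheme$points[["kegg"]] * isTRUE(kegg_relevant)
  as.integer(total)
}

#' Rank scored candidates within each QTL
#'
#' Descending by total score; ties broken alphabetically by gene name
#' (deterministic, and flagged in the output). The two highest-ranked
#' genes per QTL are marked as top candidates.
#'
#' @param cards data.frame with at least `qtl`, `name`, `score`.
#' @return `cards` with `rank` and `top_candidate` columns, ordered by
#'   (qtl, rank).
#' @export
rank_candidates <- function(cards) {
  stopifnot(all(c("qtl", "name", "score") %in% names(cards)))
  out <- do.call(rbind, lapply(split(cards, cards$qtl), function(d) {
    d <- d[order(-d$score, d$name), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d$tie_broken_alphabetically <- duplicated(d$score) | duplicated(d$score,
                                                                    fromLast = TRUE)
    d$top_candidate <- d$rank <= 2
    d
  }))
  rownames(out) <- NULL
  out
}

#' Prioritize positional candidate genes for a set of QTL intervals
#'
#' Runs the full decision tree per QTL: positional candidates in the
#' padded confidence interval, removal of genes monomorphic between the
#' lines, per-gene category flags from the variant annotations, scoring
#' with expression and KEGG evidence, and ranking with top-2 designation.
#'
#' @param intervals data.frame with `qtl`, `chr`, `start`, `stop` (one row
#'   per QTL confidence interval).
#' @param genes gene model data.frame.
#' @param variants variant annotation data.frame.
#' @param de_genes data.frame `gene`, `de_any` (see [de_by_gene()]);
#'   genes absent default to FALSE.
#' @param kegg_genes character vector of genes in relevant KEGG pathways.
#' @param scheme a [scoring_scheme()].
#' @param pad bp padding (default 1000).
#' @return ranked scorecard data.frame (`qtl`, `gene`, `name`, flags,
#'   `de_any`, `kegg`, `score`, `rank`, `top_candidate`).
#' @export
prioritize_candidates <- function(intervals, genes, variants, de_genes = NULL,
                                  kegg_genes = character(),
                                  scheme = scoring_scheme(), pad = 1000) {
  out <- list()
  for (k in seq_len(nrow(intervals))) {
    iv <- intervals[k, , drop = FALSE]
    cand <- candidate_genes(iv, genes, pad)
    cand <- polymorphic_filter(cand, variants, pad)
    if (!nrow(cand)) next
    for (i in seq_len(nrow(cand))) {
      gn <- cand[i, ]
      ann <- variants[variants$gene == gn$gene, , drop = FALSE]
      fl <- flags_from_annotations(ann)
      de <- if (!is.null(de_genes) && gn$gene %in% de_genes$gene)
        isTRUE(de_genes$de_any[de_genes$gene == gn$gene][1]) else FALSE
      kegg <- gn$gene %in% kegg_genes || gn$name %in% kegg_genes
      sc <- score_gene(fl$flags, de, kegg, scheme, fl$counts)
      out[[length(out) + 1L]] <- cbind(
        data.frame(qtl = iv$qtl[1], gene = gn$gene, name = gn$name),
        as.data.frame(as.list(fl$flags)),
        data.frame(de_any = de, kegg = kegg, score = sc))
    }
  }
  if (!length(out))
    return(data.frame(qtl = character(), gene = character(), name = character(),
                      score = integer(), rank = integer(),
                      top_candidate = logical()))
  rank_candidates(do.call(rbind, out))
}
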