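# quantile-normalize the columns of one matrix.
# reference distribution = row means of the column-sorted matrix; a value of
# average (tied) rank r receives the mean of the reference at floor(r) and
# ceiling(r).
.quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
}

#' Log2-transform and quantile-normalize an expression matrix
#'
#' Intensities are log2-transformed and quantile-normalized across samples
#' separately within each tissue (sorted-value row means assigned by rank;
#' ties receive the mean of their ranks' reference values). Zeros are
#' offset by `epsilon` before the log. A tissue with a single sample is
#' log2-transformed only, with a warning.
#'
#' @param x an [expr_matrix()] on the raw intensity scale.
#' @param epsilon offset added where intensities are 0.
#' @return an [expr_matrix()] on the log2 scale.
#' @export
normalize_expression <- function(x, epsilon = 1e-3) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$log2_scale) stopf("matrix is already on the log2 scale")
  v <- x$values
  if (any(v < 0, na.rm = TRUE)) stopf("negative intensities")
  v[v == 0] <- epsilon
  v <- log2(v)
  for (ts in unique(x$samples$tissue)) {
    cols <- which(x$samples$tissue == ts)
    if (length(cols) == 1) {
      warnf("tissue %s has a single sample; quantile normalization skipped", ts)
      next
    }
    v[, cols] <- .quantile_normalize(v[, cols, drop = FALSE])
  }
  expr_matrix(v, x$probes, x$samples, log2_scale = TRUE)
}

# Welch p-value robust to constant inputs
.welch_p <- function(a, b) {
  d <- mean(a) - mean(b)
  if (sd(a) == 0 && sd(b) == 0) return(if (abs(d) < 1e-12) 1 else 0)
  tryCatch(t.test(a, b)$p.value,
           error = function(e) if (abs(d) < 1e-12) 1 else 0)
}

#' Per-probe differential expression between two lines
#'
#' For each tissue, each probe is tested with a Welch (unequal-variance)
#' two-sample t-test between the two line groups; the fold change is the
#' difference of group means on the log2 scale (`group1 - group2`, i.e.
#' S1 - S2 with the default ordering). P-values are Benjamini-Hochberg
#' adjusted across probes within tissue.
#'
#' @param x an [expr_matrix()] on the log2 scale (see
#'   [normalize_expression()]).
#' @param groups the two line labels in (group1, group2) order; default:
#'   sorted unique lines.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame: `probe`, `gene`, `tissue`, `fc`, `p`, `p_adj`,
#'   `significant`.
#' @export
differential_expression <- function(x, groups = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!x$log2_scale) stopf("run normalize_expression() first (log2 scale required)")
  if (is.null(groups)) groups <- sort(unique(x$samples$line))
  if (length(groups) != 2) stopf("exactly two line groups are required")
  out <- list()
  for (ts in unique(x$samples$tissue)) {
    i1 <- which(x$samples$tissue == ts & x$samples$line == groups[1])
    i2 <- which(x$samples$tissue == ts & x$samples$line == groups[2])
    if (length(i1) < 2 || length(i2) < 2)
      stopf("tissue %s needs >= 2 samples per group", ts)
    v1 <- x$values[, i1, drop = FALSE]
    v2 <- x$values[, i2, drop = FALSE]
    fc <- rowMeans(v1) - rowMeans(v2)
    p <- vapply(seq_len(nrow(v1)), function(i) .welch_p(v1[i, ], v2[i, ]),
                numeric(1))
    p_adj <- p.adjust(p, method = "BH")
    out[[ts]] <- data.frame(probe = x$probes$probe, gene = x$probes$gene,
                            tissue = ts, fc = fc, p = p, p_adj = p_adj,
                            significant = p_adj < alpha)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes differentially expressed in at least one tissue
#'
#' @param de output of [differential_expression()].
#' @return data.frame `gene`, `de_any` (TRUE iff significant in >= 1 tissue).
#' @export
de_by_gene <- function(de) {
  agg <- tapply(de$significant, de$gene, any)
  data.frame(gene = names(agg), de_any = as.logical(agg), row.names = NULL)
}

#' Line-wise clustering cohesion of an expression matrix
#'
#' Computes the sample-sample Pearson correlation matrix, clusters with
#' average linkage on `1 - cor`, cuts into two clusters, and reports
#' whether the cut separates the two lines perfectly, together with a
#' cohesion score (mean within-line minus mean between-line correlation).
#' Used to ask in which tissue the two parental lines form clean
#' expression clusters.
#'
#' @param x an [expr_matrix()] (one tissue, or subset first).
#' @param tissue optional tissue to restrict to.
#' @return list: `perfect_separation` (boolean), `cohesion`, `clusters`
#'   (named cluster ids).
#' @export
cluster_by_line <- function(x, tissue = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  keep <- if (is.null(tissue)) seq_len(ncol(x$values)) else
    which(x$samples$tissue == tissue)
  if (length(keep) < 4) stopf("need at least 4 samples to cluster")
  v <- x$values[, keep, drop = FALSE]
  lines <- x$samples$line[keep]
  if (length(unique(lines)) < 2) stopf("need >= 2 line labels")
  cm <- cor(v)
  hc <- hclust(stats::as.dist(1 - cm), method = "average")
  cl <- cutree(hc, k = 2)
  tab <- table(lines, cl)
  perfect <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
  same <- outer(lines, lines, "==")
  diag(same) <- NA
  cohesion <- mean(cm[same & upper.tri(cm)], na.rm = TRUE) -
    mean(cm[!same & upper.tri(cm)], na.rm = TRUE)
  list(perfect_separation = perfect, cohesion = cohesion, clusters = cl)
}
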