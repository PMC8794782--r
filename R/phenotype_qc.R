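#' Mask phenotype outliers beyond k standard deviations
#'
#' Per trait, values with |value - mean| > k * SD are set to missing, where
#' mean and SD are computed in a single pass over the non-missing values of
#' that trait (i.e. the outlier itself is included in the estimates, and
#' the rule is not iterated). Individual measurements are masked, not whole
#' animals. Traits with SD 0 remove nothing; traits with fewer than 3
#' non-missing values are skipped with a warning.
#'
#' @param table phenotype data.frame with `id`.
#' @param traits trait columns to screen (default: all numeric columns
#'   except `litter_size`).
#' @param k SD multiplier (default 4).
#' @return list: `table` (masked copy) and `log`, a data.frame of removals
#'   (`id`, `trait`, `value`, `z`).
#' @export
remove_outliers <- function(table, traits = NULL, k = 4) {
  assert_scalar_number(k, "k", lower = 1e-12)
  table <- validate_phenotypes(table)
  if (is.null(traits))
    traits <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], "litter_size")
  log <- data.frame(id = character(), trait = character(),
                    value = numeric(), z = numeric())
  for (tr in traits) {
    x <- table[[tr]]
    ok <- !is.na(x)
    if (sum(ok) < 3) {
      warnf("trait %s has < 3 non-missing values; outlier screen skipped", tr)
      next
    }
    m <- mean(x[ok]); s <- sd(x[ok])
    if (s == 0) next
    z <- (x - m) / s
    out <- ok & abs(z) > k
    if (any(out)) {
      log <- rbind(log, data.frame(id = table$id[out], trait = tr,
                                   value = x[out], z = z[out]))
      table[[tr]][out] <- NA
    }
  }
  rownames(log) <- NULL
  list(table = table, log = log)
}

#' Area under a glucose-response curve
#'
#' Trapezoidal area of blood glucose concentration over time, the summary
#' used for oral glucose tolerance and insulin tolerance tests.
#'
#' @param times minutes, strictly increasing, length >= 2.
#' @param glucose mg/dl, same length.
#' @return area in mg/dl x min.
#' @export
compute_auc <- function(times, glucose) {
  if (length(times) < 2) stopf("AUC needs at least 2 time points")
  if (length(times) != length(glucose)) stopf("times and glucose lengths differ")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  sum(diff(times) * (glucose[-1] + glucose[-length(glucose)]) / 2)
}

#' Normality-gated trait correlation matrix
#'
#' Each trait is tested for normality (Shapiro-Wilk at
#' `normality_alpha`); a trait pair is summarized with Pearson's r iff both
#' traits pass, otherwise with Spearman's rho. Observations are
#' pairwise-complete. Constant traits yield an undefined (NA) coefficient.
#'
#' @param table phenotype data.frame.
#' @param traits trait columns (default: all numeric except `litter_size`).
#' @param normality_alpha Shapiro-Wilk level (default 0.05).
#' @return data.frame, one row per unordered pair: `trait1`, `trait2`,
#'   `method`, `r`, `p`, `n`.
#' @export
correlation_matrix <- function(table, traits = NULL, normality_alpha = 0.05) {
  table <- validate_phenotypes(table)
  if (is.null(traits))
    traits <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], "litter_size")
  if (length(traits) < 2) stopf("need at least two traits")
  normal <- vapply(traits, function(tr) {
    x <- table[[tr]][!is.na(table[[tr]])]
    if (length(x) < 3 || sd(x) == 0) return(FALSE)
    shapiro.test(x)$p.value >= normality_alpha
  }, TRUE)
  out <- list()
  for (i in seq_len(length(traits) - 1)) for (j in (i + 1):length(traits)) {
    t1 <- traits[i]; t2 <- traits[j]
    ok <- complete.cases(table[[t1]], table[[t2]])
    n <- sum(ok)
    method <- if (normal[t1] && normal[t2]) "pearson" else "spearman"
    if (n < 3 || sd(table[[t1]][ok]) == 0 || sd(table[[t2]][ok]) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(
        cor.test(table[[t1]][ok], table[[t2]][ok], method = method,
                 exact = FALSE))
      r <- unname(ct$estimate); p <- ct$p.value
    }
    out[[length(out) + 1L]] <- data.frame(trait1 = t1, trait2 = t2,
                                          method = method, r = r, p = p, n = n)
  }
  do.call(rbind, out)
}

#' Render a pairwise correlation report as a square matrix
#'
#' @param report output of [correlation_matrix()].
#' @return symmetric numeric matrix with unit diagonal.
#' @export
correlation_as_matrix <- function(report) {
  traits <- unique(c(report$trait1, report$trait2))
  m <- diag(1, length(traits))
  dimnames(m) <- list(traits, traits)
  for (k in seq_len(nrow(report))) {
    m[report$trait1[k], report$trait2[k]] <- report$r[k]
    m[report$trait2[k], report$trait1[k]] <- report$r[k]
  }
  m
}
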