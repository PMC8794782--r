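#' Scan configuration
#'
#' Bundles the tunables of the mapping engine: covariate screening level,
#' simpleM window size (markers) and variance fraction C, the genome-wide
#' alpha levels mapped to "significant" / "highly significant", the LOD
#' drop defining support intervals, and the LOD cap for numerically zero
#' p-values.
#'
#' @param covariate_alpha inclusion level for covariate screening.
#' @param simplem_window markers per simpleM window (>= 2; the emulated
#'   study used 820).
#' @param simplem_C fraction of genotypic variance the retained
#'   eigenvalues must explain (0 < C <= 1; simpleM's published default 0.995).
#' @param alpha_significant,alpha_highly genome-wide error levels (0.05 / 0.01).
#' @param lod_drop support-interval drop (default 1.5).
#' @param lod_cap LOD assigned to numerically zero p-values (default 300).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(covariate_alpha = 0.05, simplem_window = 820,
                        simplem_C = 0.995, alpha_significant = 0.05,
                        alpha_highly = 0.01, lod_drop = 1.5, lod_cap = 300) {
  assert_scalar_number(simplem_C, "simplem_C", lower = 1e-9, upper = 1)
  assert_scalar_number(simplem_window, "simplem_window", lower = 2)
  assert_scalar_number(lod_drop, "lod_drop", lower = 1e-9)
  structure(list(covariate_alpha = covariate_alpha,
                 simplem_window = as.integer(simplem_window),
                 simplem_C = simplem_C,
                 alpha_significant = alpha_significant,
                 alpha_highly = alpha_highly,
                 lod_drop = lod_drop, lod_cap = lod_cap),
            class = "scan_config")
}

#' Filter to informative markers
#'
#' Removes markers that are monomorphic across the typed individuals or
#' exceed the missingness bound, mirroring the informativeness filter that
#' reduces a dense array to the SNPs actually segregating between two
#' nearly isogenic founder lines.
#'
#' @param g a [geno_matrix()].
#' @param max_missing_fraction maximum fraction of missing genotypes.
#' @return list: `geno` (filtered [geno_matrix()]) and `log`
#'   (`marker`, `reason` for each removed marker).
#' @export
informative_markers <- function(g, max_missing_fraction = 0.1) {
  stopifnot(inherits(g, "geno_matrix"))
  miss <- rowMeans(is.na(g$geno))
  n_classes <- apply(g$geno, 1, function(x) length(unique(x[!is.na(x)])))
  mono <- n_classes <= 1
  high_miss <- miss > max_missing_fraction
  drop <- mono | high_miss
  if (all(drop)) stopf("no informative markers remain after filtering")
  log <- data.frame(marker = g$map$marker[drop],
                    reason = ifelse(mono[drop], "monomorphic", "missingness"))
  list(geno = geno_matrix(g$map[!drop, , drop = FALSE],
                          g$geno[!drop, , drop = FALSE]),
       log = log)
}

#' Screen candidate covariates for a trait
#'
#' Numeric candidates are tested by the slope t-test of a simple linear
#' regression; categorical candidates by a one-way group-means F-test. A
#' candidate is included iff p < alpha. Constant candidates (or factors
#' with a single level) are excluded with a warning.
#'
#' @param phenos phenotype data.frame.
#' @param trait trait name.
#' @param candidates covariate column names.
#' @param alpha inclusion level (default 0.05).
#' @return data.frame `covariate`, `p`, `included`.
#' @export
screen_covariates <- function(phenos, trait, candidates, alpha = 0.05) {
  stopifnot(trait %in% names(phenos), all(candidates %in% names(phenos)))
  y <- phenos[[trait]]
  rows <- lapply(candidates, function(cv) {
    x <- phenos[[cv]]
    ok <- !is.na(y) & !is.na(x)
    if (sum(ok) < 3 || length(unique(x[ok])) < 2) {
      warnf("covariate %s is constant or near-empty; excluded", cv)
      return(data.frame(covariate = cv, p = NA_real_, included = FALSE))
    }
    p <- if (is.numeric(x)) {
      fit <- lm(y[ok] ~ x[ok])
      summary(fit)$coefficients[2, 4]
    } else {
      fit <- lm(y[ok] ~ factor(x[ok]))
      a <- anova(fit)
      a$`Pr(>F)`[1]
    }
    data.frame(covariate = cv, p = p, included = p < alpha)
  })
  do.call(rbind, rows)
}

# align phenotypes with genotype columns; returns list(y, X_cov, ids)
.align_scan_data <- function(g, phenos, trait, covariates) {
  stopifnot(trait %in% names(phenos))
  ids <- intersect(colnames(g$geno), as.character(phenos$id))
  if (!length(ids)) stopf("no overlap between genotyped and phenotyped ids")
  ph <- phenos[match(ids, phenos$id), , drop = FALSE]
  keep <- !is.na(ph[[trait]])
  for (cv in covariates) keep <- keep & !is.na(ph[[cv]])
  list(ids = ids[keep], y = ph[[trait]][keep],
       cov = if (length(covariates)) ph[keep, covariates, drop = FALSE] else NULL)
}

#' Single-marker QTL scan
#'
#' Per marker, the trait is regressed on the genotype as an unordered
#' 3-level factor (plus any covariates) and compared with the
#' covariates-only null by a nested-model F-test on the individuals
#' complete for that marker; LOD = -log10(p). Markers with fewer than two
#' observed genotype classes, or no residual degrees of freedom, get a
#' missing LOD and a log entry. A perfect fit (zero residual variance) is
#' reported at the LOD cap.
#'
#' @param g a [geno_matrix()].
#' @param phenos phenotype data.frame.
#' @param trait trait name.
#' @param covariates covariate column names to adjust for.
#' @param lod_cap LOD cap (default 300).
#' @param additive if TRUE, model the genotype as allele dosage (1 df)
#'   instead of a 3-level factor.
#' @return data.frame of class `lod_curve`: `marker`, `chr`, `pos`, `lod`,
#'   `n`, ordered by (chr, pos); attribute `skipped` lists markers without
#'   a valid test.
#' @export
qtl_scan <- function(g, phenos, trait, covariates = character(),
                     lod_cap = 300, additive = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  ad <- .align_scan_data(g, phenos, trait, covariates)
  y <- ad$y
  G <- g$geno[, ad$ids, drop = FALSE]
  m <- nrow(G)
  if (length(y) < 4) stopf("fewer than 4 usable individuals")
  if (!length(covariates) && !additive) {
    res <- .scan_anova_fast(G, y)
  } else {
    res <- .scan_lm(G, y, ad$cov, additive)
  }
  p <- res$p
  lod <- ifelse(is.na(p), NA_real_, pmin(-log10(pmax(p, 1e-300)), lod_cap))
  out <- data.frame(marker = g$map$marker, chr = g$map$chr, pos = g$map$pos,
                    lod = lod, n = res$n)
  attr(out, "skipped") <- g$map$marker[is.na(lod)]
  class(out) <- c("lod_curve", "data.frame")
  out
}

# vectorized one-way ANOVA across all markers (no covariates).
.scan_anova_fast <- function(G, y) {
  obs <- !is.na(G)
  n_i <- rowSums(obs)
  y2 <- y^2
  Sy <- obs %*% y
  Syy <- obs %*% y2
  ss_tot <- Syy - Sy^2 / n_i
  ss_b <- -Sy^2 / n_i
  classes <- 0L
  for (k in 0:2) {
    Ik <- !is.na(G) & G == k
    nk <- rowSums(Ik)
    Sk <- Ik %*% y
    term <- ifelse(nk > 0, Sk^2 / pmax(nk, 1), 0)
    ss_b <- ss_b + term
    classes <- classes + (nk > 0)
  }
  df1 <- classes - 1L
  df2 <- n_i - classes
  ss_w <- pmax(ss_tot - ss_b, 0)
  valid <- df1 >= 1 & df2 >= 1 & ss_tot > 0
  Fst <- (ss_b / pmax(df1, 1)) / pmax(ss_w / pmax(df2, 1), .Machine$double.xmin)
  p <- rep(NA_real_, nrow(G))
  p[valid] <- pf(Fst[valid], df1[valid], df2[valid], lower.tail = FALSE)
  list(p = as.vector(p), n = as.vector(n_i))
}

# per-marker lm fits (covariate-adjusted and/or additive coding)
.scan_lm <- function(G, y, cov, additive) {
  m <- nrow(G)
  p <- rep(NA_real_, m); nn <- integer(m)
  for (i in seq_len(m)) {
    gi <- G[i, ]
    ok <- !is.na(gi)
    nn[i] <- sum(ok)
    cls <- unique(gi[ok])
    if (length(cls) < 2) next
    dat <- data.frame(y = y[ok],
                      geno = if (additive) gi[ok] else factor(gi[ok]))
    if (!is.null(cov)) dat <- cbind(dat, cov[ok, , drop = FALSE])
    covs <- setdiff(names(dat), c("y", "geno"))
    f_null <- if (length(covs))
      stats::reformulate(covs, response = "y") else y ~ 1
    f_full <- stats::reformulate(c(covs, "geno"), response = "y")
    full <- lm(f_full, data = dat)
    if (full$df.residual < 1) next
    null <- lm(f_null, data = dat)
    a <- anova(null, full)
    p[i] <- a$`Pr(>F)`[2]
    if (is.na(p[i]) && a$`Sum of Sq`[2] > 0) p[i] <- 0  # perfect fit
  }
  list(p = p, n = nn)
}

#' simpleM effective number of independent tests
#'
#' Markers are partitioned, per chromosome, into consecutive windows of at
#' most `window` markers. In each window the pairwise genotype-code
#' correlation matrix (pairwise-complete observations) is eigendecomposed
#' and the window's effective test count is the smallest k whose top-k
#' eigenvalues reach a fraction C of the total; the genome-wide Meff is the
#' sum over windows. Constant markers contribute zero correlation (with a
#' warning); small negative eigenvalues from pairwise-complete estimation
#' are clamped to zero.
#'
#' @param g a [geno_matrix()].
#' @param window maximum markers per window (>= 2).
#' @param C variance fraction (default 0.995, the method's published default).
#' @return integer Meff; attribute `windows` gives the per-window counts.
#' @export
simple_m <- function(g, window = 820, C = 0.995) {
  stopifnot(inherits(g, "geno_matrix"))
  assert_scalar_number(window, "window", lower = 2)
  assert_scalar_number(C, "C", lower = 1e-9, upper = 1)
  per_window <- integer(0)
  for (ch in unique(g$map$chr)) {
    idx <- which(g$map$chr == ch)
    starts <- seq(1, length(idx), by = window)
    for (s in starts) {
      w <- idx[s:min(s + window - 1, length(idx))]
      per_window <- c(per_window, .meff_window(g$geno[w, , drop = FALSE], C))
    }
  }
  structure(sum(per_window), windows = per_window)
}

.meff_window <- function(G, C) {
  if (nrow(G) == 1) return(1L)
  sds <- apply(G, 1, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds)))
    warnf("%d constant marker(s) in simpleM window; correlations set to 0",
          sum(sds == 0 | is.na(sds)))
  R <- suppressWarnings(cor(t(G), use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= C - 1e-12)[1])
}

#' Bonferroni LOD threshold from an effective test count
#'
#' `-log10(alpha / meff)`: the genome-wide LOD threshold after Bonferroni
#' correction over `meff` effective tests.
#'
#' @param alpha genome-wide error level (0 < alpha < 1).
#' @param meff effective number of tests (>= 1).
#' @return LOD threshold.
#' @export
bonferroni_lod_threshold <- function(alpha, meff) {
  assert_scalar_number(alpha, "alpha", lower = 1e-300, upper = 1 - 1e-12)
  assert_scalar_number(meff, "meff", lower = 1)
  -log10(alpha / meff)
}

#' LOD-drop support interval on one chromosome
#'
#' The peak is the marker with maximal LOD (ties: lower position). The core
#' region is the maximal contiguous run of markers containing the peak with
#' LOD >= peak - drop; the reported interval extends one marker beyond the
#' run on each side (clamped to the chromosome ends), i.e. the first SNP
#' upstream/downstream of the drop region.
#'
#' @param curve a `lod_curve` data.frame.
#' @param chromosome chromosome name.
#' @param drop LOD drop (default 1.5).
#' @return one-row data.frame: `chr`, `start`, `top`, `stop`, `top_marker`,
#'   `top_lod`.
#' @export
lod_drop_interval <- function(curve, chromosome, drop = 1.5) {
  cc <- curve[curve$chr == chromosome & !is.na(curve$lod), , drop = FALSE]
  if (!nrow(cc)) stopf("no non-missing LOD on chromosome %s", chromosome)
  cc <- cc[order(cc$pos), , drop = FALSE]
  top_i <- which(cc$lod == max(cc$lod))[1]
  thr <- cc$lod[top_i] - drop
  in_run <- cc$lod >= thr
  lo <- top_i; while (lo > 1 && in_run[lo - 1]) lo <- lo - 1
  hi <- top_i; while (hi < nrow(cc) && in_run[hi + 1]) hi <- hi + 1
  start_i <- max(lo - 1, 1)
  stop_i <- min(hi + 1, nrow(cc))
  data.frame(chr = chromosome, start = cc$pos[start_i], top = cc$pos[top_i],
             stop = cc$pos[stop_i], top_marker = cc$marker[top_i],
             top_lod = cc$lod[top_i])
}

#' Genotype class means, contrasts and variance explained at a marker
#'
#' Class means are computed over all genotyped animals (array plus
#' targeted follow-up), the design that de-biases effect estimates after
#' selective genotyping. Variance explained is 100 x the genotype-factor
#' sum of squares over the total sum of squares of the fitted model
#' (covariates, if any, entered first).
#'
#' @param g a [geno_matrix()].
#' @param phenos phenotype data.frame.
#' @param trait trait name.
#' @param marker marker id.
#' @param covariates covariate columns entered before the genotype factor.
#' @return one-row data.frame: `marker`, `n`, `mean_s1`, `mean_het`,
#'   `mean_s2`, `delta_s1_het`, `delta_s1_s2`, `var_explained`.
#' @export
genotype_effects <- function(g, phenos, trait, marker, covariates = character()) {
  stopifnot(inherits(g, "geno_matrix"), marker %in% g$map$marker)
  ad <- .align_scan_data(g, phenos, trait, covariates)
  gi <- g$geno[marker, ad$ids]
  ok <- !is.na(gi)
  if (!any(ok)) stopf("no genotyped+phenotyped animals at %s", marker)
  y <- ad$y[ok]; gi <- gi[ok]
  if (sd(y) == 0 && length(unique(gi)) < 2)
    stopf("trait constant and marker monomorphic at %s", marker)
  cm <- function(k) if (any(gi == k)) mean(y[gi == k]) else NA_real_
  mean_s2 <- cm(0L); mean_het <- cm(1L); mean_s1 <- cm(2L)
  ve <- NA_real_
  if (length(unique(gi)) >= 2) {
    dat <- data.frame(y = y, geno = factor(gi))
    if (length(covariates)) dat <- cbind(dat, ad$cov[ok, , drop = FALSE])
    f <- stats::reformulate(c(setdiff(names(dat), c("y", "geno")), "geno"),
                            response = "y")
    a <- anova(lm(f, data = dat))
    ve <- 100 * a["geno", "Sum Sq"] / sum(a[, "Sum Sq"])
  }
  data.frame(marker = marker, n = length(y),
             mean_s1 = mean_s1, mean_het = mean_het, mean_s2 = mean_s2,
             delta_s1_het = mean_s1 - mean_het,
             delta_s1_s2 = mean_s1 - mean_s2,
             var_explained = ve)
}

#' Nonparametric validation of a mapped marker
#'
#' Shapiro-Wilk on the residuals of the marker model; if residuals are
#' non-normal (p < `normality_alpha`), a Kruskal-Wallis test across
#' genotype classes validates the association. `confirmed` is TRUE when
#' residuals are normal, or when the Kruskal-Wallis p falls below `alpha`;
#' it is NA when a class has < 2 observations (test skipped).
#'
#' @param g a [geno_matrix()].
#' @param phenos phenotype data.frame.
#' @param trait trait name.
#' @param marker marker id.
#' @param covariates covariates of the fitted model.
#' @param alpha the marker's parametric level used for the KW comparison.
#' @param normality_alpha Shapiro-Wilk gate (default 0.05).
#' @return list: `residual_normality_p`, `kruskal_wallis_p`, `confirmed`.
#' @export
nonparametric_check <- function(g, phenos, trait, marker,
                                covariates = character(), alpha = 0.05,
                                normality_alpha = 0.05) {
  stopifnot(marker %in% g$map$marker)
  ad <- .align_scan_data(g, phenos, trait, covariates)
  gi <- g$geno[marker, ad$ids]
  ok <- !is.na(gi)
  y <- ad$y[ok]; gi <- gi[ok]
  dat <- data.frame(y = y, geno = factor(gi))
  if (length(covariates)) dat <- cbind(dat, ad$cov[ok, , drop = FALSE])
  f <- stats::reformulate(setdiff(names(dat), "y"), response = "y")
  res <- stats::residuals(lm(f, data = dat))
  if (sd(res) == 0)
    return(list(residual_normality_p = NA_real_, kruskal_wallis_p = NA_real_,
                confirmed = NA))
  swp <- shapiro.test(res)$p.value
  if (swp >= normality_alpha)
    return(list(residual_normality_p = swp, kruskal_wallis_p = NA_real_,
                confirmed = TRUE))
  if (any(table(gi) < 2))
    return(list(residual_normality_p = swp, kruskal_wallis_p = NA_real_,
                confirmed = NA))
  kwp <- kruskal.test(y, factor(gi))$p.value
  list(residual_normality_p = swp, kruskal_wallis_p = kwp,
       confirmed = kwp < alpha)
}

#' Two-stage QTL scan under selective genotyping
#'
#' Stage 1 scans the selectively genotyped subset (phenotypic tails) and
#' declares peaks per chromosome at the significant Bonferroni/simpleM
#' threshold, with 1.5-LOD-drop support intervals. Stage 2 refits every
#' peak marker on all animals (array plus targeted genotypes) for the
#' reported LOD, class means and variance explained, counteracting the
#' effect-size bias that tail selection introduces. Peak markers absent
#' from the full genotype set keep their stage-1 estimates and are flagged
#' `"unconfirmed"`.
#'
#' @param g_selected genotypes of the selectively genotyped animals.
#' @param g_full genotypes (at least at the peak markers) of all animals.
#' @param phenos phenotype data.frame covering all animals.
#' @param trait trait name.
#' @param covariates covariates for the marker model.
#' @param config a [scan_config()].
#' @param qtl_prefix stem used to name detected QTL.
#' @return data.frame shaped like a QTL summary table: `trait`, `qtl`,
#'   `chr`, `start`, `top`, `stop`, `lod`, `var_explained`, `mean_s1`,
#'   `delta_s1_het`, `delta_s1_s2`, `n`, `status`; zero rows when no peak
#'   reaches the threshold.
#' @export
two_stage_scan <- function(g_selected, g_full, phenos, trait,
                           covariates = character(), config = scan_config(),
                           qtl_prefix = "q") {
  stopifnot(inherits(config, "scan_config"))
  curve <- qtl_scan(g_selected, phenos, trait, covariates,
                    lod_cap = config$lod_cap)
  meff <- simple_m(g_selected, config$simplem_window, config$simplem_C)
  thr <- bonferroni_lod_threshold(config$alpha_significant, meff)
  out <- list()
  for (ch in unique(curve$chr)) {
    cc <- curve[curve$chr == ch & !is.na(curve$lod), , drop = FALSE]
    if (!nrow(cc) || max(cc$lod) < thr) next
    iv <- lod_drop_interval(curve, ch, config$lod_drop)
    mk <- iv$top_marker
    in_full <- mk %in% g_full$map$marker
    if (in_full) {
      eff <- genotype_effects(g_full, phenos, trait, mk, covariates)
      c2 <- qtl_scan(subset_geno(g_full, markers = mk), phenos, trait,
                     covariates, lod_cap = config$lod_cap)
      lod2 <- c2$lod[1]; n2 <- c2$n[1]
      status <- "confirmed"
    } else {
      eff <- genotype_effects(g_selected, phenos, trait, mk, covariates)
      lod2 <- iv$top_lod; n2 <- eff$n
      status <- "unconfirmed"
    }
    out[[length(out) + 1L]] <- data.frame(
      trait = trait, qtl = sprintf("%s_%s", qtl_prefix, ch), chr = ch,
      start = iv$start, top = iv$top, stop = iv$stop,
      lod = lod2, var_explained = eff$var_explained,
      mean_s1 = eff$mean_s1, delta_s1_het = eff$delta_s1_het,
      delta_s1_s2 = eff$delta_s1_s2, n = n2, status = status)
  }
  if (!length(out))
    return(data.frame(trait = character(), qtl = character(), chr = character(),
                      start = numeric(), top = numeric(), stop = numeric(),
                      lod = numeric(), var_explained = numeric(),
                      mean_s1 = numeric(), delta_s1_het = numeric(),
                      delta_s1_s2 = numeric(), n = integer(),
                      status = character()))
  do.call(rbind, out)
}
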