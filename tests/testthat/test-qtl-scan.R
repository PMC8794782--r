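test_that("informative-marker filtering removes exactly the monomorphic markers", {
  set.seed(2)
  codes <- matrix(rbinom(100 * 40, 2, 0.5), 100, 40)
  mono_rows <- sample(100, 10)
  codes[mono_rows, ] <- 2L
  g <- geno_from_codes(codes)
  res <- informative_markers(g)
  expect_setequal(res$log$marker, sprintf("m%03d", sort(mono_rows)))
  expect_identical(nrow(res$geno$geno), 90L)
  expect_true(all(res$log$reason == "monomorphic"))
  # missingness bound
  codes2 <- matrix(rbinom(2 * 40, 2, 0.5), 2, 40)
  codes2[1, 1:20] <- NA
  res2 <- informative_markers(geno_from_codes(codes2), max_missing_fraction = 0.1)
  expect_identical(res2$log$reason, "missingness")
  expect_error(informative_markers(geno_from_codes(matrix(1L, 2, 10))),
               "no informative")
})

test_that("covariate screening includes real signals and excludes noise", {
  set.seed(3)
  ph <- pheno_table(sprintf("i%03d", 1:400), y = rnorm(400))
  ph$self <- ph$y
  scr <- suppressWarnings(screen_covariates(ph, "y", "self"))
  expect_true(scr$included)
  expect_lt(scr$p, 1e-10)
  excl <- vapply(1:50, function(s) {
    set.seed(500 + s)
    ph$noise <- rnorm(400)
    !screen_covariates(ph, "y", "noise")$included
  }, TRUE)
  expect_gte(mean(excl), 0.9)
  ph$onelevel <- "x"
  expect_warning(scr3 <- screen_covariates(ph, "y", "onelevel"), "constant")
  expect_false(scr3$included)
})

test_that("a perfect genotype-phenotype fit is reported at the LOD cap", {
  g <- hwe_geno(5, 60, seed = 4)
  ph <- pheno_table(colnames(g$geno), y = as.numeric(g$geno[3, ]))
  cu <- qtl_scan(g, ph, "y")
  expect_equal(cu$lod[3], 300)
  cu2 <- qtl_scan(g, ph, "y", lod_cap = 50)
  expect_equal(cu2$lod[3], 50)
})

test_that("the fast scan matches per-marker linear-model F-tests (with missing data)", {
  set.seed(6)
  g <- hwe_geno(20, 80, seed = 6)
  g$geno[cbind(sample(20, 15, TRUE), sample(80, 15, TRUE))] <- NA
  ph <- pheno_table(colnames(g$geno),
                    y = 0.5 * ifelse(is.na(g$geno[4, ]), 0, g$geno[4, ]) + rnorm(80))
  cu <- qtl_scan(g, ph, "y")
  # oracle: explicit lm factor fit per marker
  for (i in c(1, 4, 9, 17)) {
    gi <- g$geno[i, ]
    ok <- !is.na(gi)
    fit <- lm(ph$y[ok] ~ factor(gi[ok]))
    p_lm <- anova(fit)$`Pr(>F)`[1]
    expect_equal(cu$lod[i], -log10(p_lm), tolerance = 1e-8)
    expect_equal(cu$n[i], sum(ok))
  }
})

test_that("covariate-adjusted scans use the nested-model F-test", {
  set.seed(7)
  g <- hwe_geno(6, 120, seed = 7)
  litter <- sample(4:12, 120, TRUE)
  y <- 0.6 * g$geno[2, ] + 0.3 * litter + rnorm(120)
  ph <- pheno_table(colnames(g$geno), y = y, litter_size = litter)
  cu <- qtl_scan(g, ph, "y", covariates = "litter_size")
  full <- lm(y ~ litter + factor(g$geno[2, ]))
  null <- lm(y ~ litter)
  expect_equal(cu$lod[2], -log10(anova(null, full)$`Pr(>F)`[2]),
               tolerance = 1e-8)
})

test_that("a null scan stays below the simpleM/Bonferroni threshold", {
  g <- small_ail(n = 200, n_gen = 9, n_chr = 5, n_mark = 100, seed = 8)
  meff <- simple_m(g, window = 100)
  thr <- bonferroni_lod_threshold(0.05, meff)
  below <- vapply(1:20, function(s) {
    set.seed(900 + s)
    ph <- pheno_table(colnames(g$geno), y = rnorm(200))
    max(qtl_scan(g, ph, "y")$lod, na.rm = TRUE) < thr
  }, TRUE)
  expect_gte(mean(below), 0.9)
})

test_that("scan LOD is invariant to affine trait rescaling", {
  g <- small_ail(n = 120, n_mark = 20, seed = 9)
  ph <- simulate_phenotypes(g, list(qtl_spec("t", g$map$marker[7],
                                             additive_effect = 0.5)), seed = 2)
  cu1 <- qtl_scan(g, ph, "t")
  ph$t <- 100 + 7.3 * ph$t
  cu2 <- qtl_scan(g, ph, "t")
  expect_equal(cu1$lod, cu2$lod, tolerance = 1e-9)
})

test_that("markers with fewer than two observed classes get a missing LOD", {
  codes <- rbind(rep(1L, 20), rbinom(20, 2, 0.5))
  g <- geno_from_codes(codes)
  ph <- pheno_table(colnames(g$geno), y = rnorm(20))
  cu <- qtl_scan(g, ph, "y")
  expect_true(is.na(cu$lod[1]))
  expect_identical(attr(cu, "skipped"), "m001")
})

# --- simpleM ----------------------------------------------------------------

test_that("simpleM approaches the marker count for independent markers", {
  g <- hwe_geno(30, 800, seed = 10)
  meff <- simple_m(g, window = 30)
  expect_lte(meff, 30L)
  expect_gte(meff, 27L)   # >= 0.9 M for orthogonal markers
})

test_that("duplicated markers collapse to a single effective test", {
  base <- rbinom(50, 2, 0.5)
  g <- geno_from_codes(matrix(rep(base, each = 10), 10, 50))
  expect_identical(as.integer(simple_m(g, window = 10)), 1L)
})

test_that("windowed simpleM equals a direct eigendecomposition oracle", {
  g <- small_ail(n = 300, n_chr = 1, n_mark = 50, seed = 11)
  meff <- simple_m(g, window = 25, C = 0.995)
  # oracle: per 25-marker window, PCA of the standardized genotypes
  oracle <- 0L
  for (w in list(1:25, 26:50)) {
    pc <- prcomp(t(g$geno[w, ]), center = TRUE, scale. = TRUE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    oracle <- oracle + which(cum >= 0.995)[1]
  }
  expect_identical(as.integer(meff), as.integer(oracle))
  expect_identical(length(attr(meff, "windows")), 2L)
})

test_that("a constant marker inside a window is tolerated with a warning", {
  codes <- rbind(matrix(rbinom(5 * 40, 2, 0.5), 5, 40), rep(2L, 40))
  g <- geno_from_codes(codes)
  expect_warning(meff <- simple_m(g, window = 6), "constant")
  expect_gte(as.integer(meff), 1L)
})

# --- thresholds and intervals ----------------------------------------------

test_that("Bonferroni LOD thresholds follow -log10(alpha/meff)", {
  expect_equal(bonferroni_lod_threshold(0.05, 1), 1.30103, tolerance = 1e-5)
  # monotone in meff and in decreasing alpha
  ms <- c(1, 10, 100, 849, 5000)
  expect_true(all(diff(vapply(ms, bonferroni_lod_threshold, 1, alpha = 0.05)) > 0))
  as <- c(0.1, 0.05, 0.01, 0.001)   # decreasing alpha -> rising threshold
  expect_true(all(diff(vapply(as, bonferroni_lod_threshold, 1, meff = 849)) > 0))
  expect_error(bonferroni_lod_threshold(0, 10))
  expect_error(bonferroni_lod_threshold(0.05, 0))
})

test_that("the 1.5-LOD-drop interval extends one marker beyond the core run", {
  curve <- data.frame(marker = sprintf("m%d", 1:7), chr = "chr1",
                      pos = (1:7) * 1e6,
                      lod = c(1, 3, 6, 8, 6.4, 6.6, 2), n = 100)
  class(curve) <- c("lod_curve", "data.frame")
  iv <- lod_drop_interval(curve, "chr1")
  expect_equal(iv$top, 4e6)
  expect_equal(iv$start, 3e6)   # first marker before the core run {4 Mb}
  expect_equal(iv$stop, 5e6)
})

test_that("interval boundaries clamp at chromosome ends", {
  one <- data.frame(marker = "m1", chr = "chrX", pos = 5e6, lod = 7, n = 10)
  iv1 <- lod_drop_interval(one, "chrX")
  expect_true(iv1$start == 5e6 && iv1$top == 5e6 && iv1$stop == 5e6)
  mono <- data.frame(marker = sprintf("m%d", 1:5), chr = "chr2",
                     pos = (1:5) * 1e6, lod = c(9, 8.8, 5, 3, 1), n = 10)
  iv2 <- lod_drop_interval(mono, "chr2")
  expect_equal(iv2$start, 1e6)  # decreasing from the first marker
  expect_equal(iv2$top, 1e6)
  expect_error(lod_drop_interval(mono, "chr9"), "chromosome")
})

test_that("ties at the peak resolve to the lower position", {
  curve <- data.frame(marker = sprintf("m%d", 1:4), chr = "c",
                      pos = (1:4) * 1e5, lod = c(2, 5, 5, 2), n = 10)
  expect_equal(lod_drop_interval(curve, "c")$top, 2e5)
})

# --- effects ----------------------------------------------------------------

test_that("genotype effects are exact when the phenotype equals the code", {
  g <- hwe_geno(3, 90, seed = 12)
  ph <- pheno_table(colnames(g$geno), y = as.numeric(g$geno[2, ]))
  eff <- suppressWarnings(genotype_effects(g, ph, "y", "m002"))
  expect_equal(eff$mean_s1, 2)
  expect_equal(eff$mean_het, 1)
  expect_equal(eff$mean_s2, 0)
  expect_equal(eff$delta_s1_het, 1)
  expect_equal(eff$delta_s1_s2, 2)
  expect_equal(eff$var_explained, 100)
})

test_that("variance explained stays small for a null marker", {
  g <- hwe_geno(1, 397, seed = 13)
  small <- vapply(1:50, function(s) {
    set.seed(1300 + s)
    ph <- pheno_table(colnames(g$geno), y = rnorm(397))
    genotype_effects(g, ph, "y", "m001")$var_explained < 3
  }, TRUE)
  expect_gte(mean(small), 0.9)
})

test_that("large samples recover the planted allele substitution effect", {
  g <- hwe_geno(1, 10000, seed = 14)
  set.seed(14)
  ph <- pheno_table(colnames(g$geno),
                    y = 0.5 * as.numeric(g$geno[1, ]) + rnorm(10000))
  eff <- genotype_effects(g, ph, "y", "m001")
  expect_lt(abs(eff$delta_s1_s2 - 1.0), 0.1)
})

# --- nonparametric validation ----------------------------------------------

test_that("normal residuals skip the Kruskal-Wallis fallback", {
  g <- hwe_geno(1, 200, seed = 15)
  set.seed(15)
  ph <- pheno_table(colnames(g$geno),
                    y = 0.8 * as.numeric(g$geno[1, ]) + rnorm(200))
  chk <- nonparametric_check(g, ph, "y", "m001")
  expect_gte(chk$residual_normality_p, 0.05)
  expect_true(is.na(chk$kruskal_wallis_p))
  expect_true(chk$confirmed)
})

test_that("heavy-tailed noise triggers Kruskal-Wallis, which confirms a strong QTL", {
  g <- hwe_geno(1, 397, seed = 16)
  ok <- vapply(1:20, function(s) {
    set.seed(1600 + s)
    ph <- pheno_table(colnames(g$geno),
                      y = 1.2 * as.numeric(g$geno[1, ]) + stats::rt(397, df = 2))
    chk <- nonparametric_check(g, ph, "y", "m001")
    !is.na(chk$kruskal_wallis_p) && chk$kruskal_wallis_p < 0.05 && isTRUE(chk$confirmed)
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("the Kruskal-Wallis statistic matches the brute-force rank formula", {
  g <- geno_from_codes(matrix(c(0L, 0L, 1L, 1L, 2L, 2L), 1, 6))
  ph <- pheno_table(colnames(g$geno), y = c(1, 2, 3, 4, 5, 6))
  # forcing the nonparametric branch: H = 12/(N(N+1)) sum R_i^2/n_i - 3(N+1)
  H <- 12 / (6 * 7) * ((1 + 2)^2 / 2 + (3 + 4)^2 / 2 + (5 + 6)^2 / 2) - 3 * 7
  chk <- nonparametric_check(g, ph, "y", "m001", normality_alpha = 1)
  expect_equal(chk$kruskal_wallis_p, stats::pchisq(H, 2, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("classes with fewer than two observations leave the verdict unknown", {
  g <- geno_from_codes(matrix(c(0L, 0L, 0L, 1L, 1L, 2L), 1, 6))
  ph <- pheno_table(colnames(g$geno), y = c(5, 6, 4, 20, 21, 50))
  chk <- nonparametric_check(g, ph, "y", "m001", normality_alpha = 1)
  expect_true(is.na(chk$confirmed))
})

# --- two-stage scan ---------------------------------------------------------

test_that("with full-cohort selection the two stages agree exactly", {
  g <- small_ail(n = 120, n_chr = 1, n_mark = 30, seed = 17)
  q <- g$map$marker[15]
  ph <- simulate_phenotypes(g, list(qtl_spec("t", q, additive_effect = 1.2,
                                             noise_sd = 0.5)), seed = 18)
  cfg <- scan_config(simplem_window = 30)
  res <- two_stage_scan(g, g, ph, "t", config = cfg)
  expect_identical(nrow(res), 1L)
  expect_identical(res$status, "confirmed")
  stage1 <- genotype_effects(g, ph, "t", marker = g$map$marker[
    which(g$map$pos == res$top)])
  expect_equal(res$delta_s1_s2, stage1$delta_s1_s2)
  expect_equal(res$var_explained, stage1$var_explained)
})

test_that("a null trait yields an empty QTL table in most replicates", {
  g <- small_ail(n = 150, n_chr = 2, n_mark = 40, seed = 19)
  cfg <- scan_config(simplem_window = 40)
  empty <- vapply(1:10, function(s) {
    set.seed(1900 + s)
    ph <- pheno_table(colnames(g$geno), t = rnorm(150))
    sel <- select_tails(ph, "t", 100)
    nrow(two_stage_scan(subset_geno(g, individuals = sel), g, ph, "t",
                        config = cfg)) == 0
  }, TRUE)
  expect_gte(mean(empty), 0.9)
})

test_that("peak markers missing from the follow-up genotypes are flagged unconfirmed", {
  g <- small_ail(n = 150, n_chr = 1, n_mark = 30, seed = 20)
  q <- g$map$marker[15]
  ph <- simulate_phenotypes(g, list(qtl_spec("t", q, additive_effect = 1.5,
                                             noise_sd = 0.5)), seed = 21)
  sel <- select_tails(ph, "t", 100)
  g_sel <- subset_geno(g, individuals = sel)
  cu <- qtl_scan(g_sel, ph, "t")
  top_mk <- cu$marker[which.max(cu$lod)]
  g_full_missing <- subset_geno(g, markers = setdiff(g$map$marker, top_mk))
  res <- two_stage_scan(g_sel, g_full_missing, ph, "t",
                        config = scan_config(simplem_window = 30))
  expect_identical(res$status, "unconfirmed")
})
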