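#' Pairwise causal modeling of a shared QTL
#'
#' For a QTL detected for two traits, three generative decompositions of
#' the joint Gaussian likelihood of (T1, T2) given the genotype Q are
#' compared, each the sum of two linear-model components with the genotype
#' entering as an unordered 3-level factor:
#'
#' * independent: \[T1 | Q\] + \[T2 | Q\] — the QTL affects both traits
#'   directly;
#' * causal (T1 -> T2): \[T1 | Q\] + \[T2 | T1\] — the QTL affects T1,
#'   which in turn drives T2;
#' * reactive (T2 -> T1): \[T2 | Q\] + \[T1 | T2\].
#'
#' Models are compared by the small-sample-corrected Akaike criterion
#' (AICc; the models are non-nested, so no likelihood-ratio test applies).
#' The verdict is the best model iff it beats the runner-up by at least
#' `gap` AICc units AND the winner passes a goodness-of-fit screen
#' (Shapiro-Wilk p >= `gof_alpha` on each component's residuals);
#' otherwise the causality is undetermined.
#'
#' @param q genotype codes (0/1/2) at the shared QTL marker.
#' @param t1,t2 trait vectors, same length as `q`.
#' @param gap AICc margin required to call a winner (default 2).
#' @param trait_names labels for the pair (default `c("T1", "T2")`).
#' @param gof_alpha residual-normality screen level (default 0.01).
#' @param min_n minimum complete cases (default 30).
#' @return object of class `causal_verdict`: list with `traits`, `fits`
#'   (data.frame: model, logLik, k, aicc), `verdict` (one of
#'   `independent`, `causal_T1_to_T2`, `reactive_T2_to_T1`,
#'   `undetermined`), `margin`.
#' @export
fit_causal_models <- function(q, t1, t2, gap = 2, trait_names = c("T1", "T2"),
                              gof_alpha = 0.01, min_n = 30) {
  ok <- !is.na(q) & !is.na(t1) & !is.na(t2)
  q <- q[ok]; t1 <- t1[ok]; t2 <- t2[ok]
  n <- length(q)
  if (n < min_n) stopf("need at least %d complete cases (got %d)", min_n, n)
  if (length(unique(q)) < 2) stopf("genotype has a single class")
  if (sd(t1) == 0 || sd(t2) == 0) stopf("constant trait")
  Qf <- factor(q)
  comp <- function(y, x) {
    fit <- lm(y ~ x)
    ll <- logLik(fit)
    list(ll = as.numeric(ll), k = attr(ll, "df"),
         res = stats::residuals(fit))
  }
  models <- list(
    independent       = list(comp(t1, Qf), comp(t2, Qf)),
    causal_T1_to_T2   = list(comp(t1, Qf), comp(t2, t1)),
    reactive_T2_to_T1 = list(comp(t2, Qf), comp(t1, t2)))
  fits <- do.call(rbind, lapply(names(models), function(mn) {
    cs <- models[[mn]]
    ll <- cs[[1]]$ll + cs[[2]]$ll
    k <- cs[[1]]$k + cs[[2]]$k
    aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
    data.frame(model = mn, logLik = ll, k = k, aicc = aicc)
  }))
  ord <- order(fits$aicc)
  best <- fits$model[ord[1]]
  margin <- fits$aicc[ord[2]] - fits$aicc[ord[1]]
  if (!is.finite(margin)) margin <- 0       # degenerate (perfect) fits tie
  verdict <- "undetermined"
  if (margin >= gap) {
    res_ok <- vapply(models[[best]], function(cmp) {
      r <- cmp$res
      if (sd(r) == 0 || length(r) < 3) return(FALSE)   # degenerate component
      shapiro.test(r)$p.value >= gof_alpha
    }, TRUE)
    if (all(res_ok)) verdict <- best
  }
  structure(list(traits = trait_names, n = n, fits = fits,
                 verdict = verdict, margin = margin, gap = gap),
            class = "causal_verdict")
}

#' @export
print.causal_verdict <- function(x, ...) {
  cat(sprintf("<causal_verdict> (%s, %s): %s (AICc margin %.2f, n = %d)\n",
              x$traits[1], x$traits[2], x$verdict, x$margin, x$n))
  print(x$fits, row.names = FALSE)
  invisible(x)
}

#' Label per-trait QTL effects from pairwise causal verdicts
#'
#' Applies the direct/indirect rule to a set of verdicts over the same QTL:
#' an independent verdict labels both traits direct; a causal verdict
#' labels the upstream trait direct and the downstream one indirect;
#' undetermined leaves both unlabeled. Conflicting labels for a trait
#' across pairs are reported, not resolved.
#'
#' @param verdicts list of [fit_causal_models()] results for one QTL.
#' @return list: `labels` (named character: `direct` / `indirect` per
#'   trait), `conflicts` (traits with contradictory labels).
#' @export
classify_qtl_effects <- function(verdicts) {
  stopifnot(all(vapply(verdicts, inherits, TRUE, "causal_verdict")))
  lab <- list()
  add <- function(lab, trait, value) {
    lab[[trait]] <- unique(c(lab[[trait]], value))
    lab
  }
  for (v in verdicts) {
    tr <- v$traits
    lab <- switch(v$verdict,
      independent       = add(add(lab, tr[1], "direct"), tr[2], "direct"),
      causal_T1_to_T2   = add(add(lab, tr[1], "direct"), tr[2], "indirect"),
      reactive_T2_to_T1 = add(add(lab, tr[2], "direct"), tr[1], "indirect"),
      undetermined      = lab)
  }
  conflicts <- names(lab)[vapply(lab, length, 1L) > 1]
  labels <- vapply(lab, function(x) if (length(x) == 1) x else "conflict", "")
  list(labels = labels, conflicts = conflicts)
}
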