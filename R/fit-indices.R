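#' Fit indices: chi-square and CFI
#'
#' Computes the comparative fit index
#' `CFI = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)`, clipped to
#' \[0, 1\]. The baseline defaults to the independence model (free variances,
#' zero covariances) fitted to the same sample moments, which has the closed
#' form `F_b = sum(log diag(S)) - log det(S)` per group with
#' `df_b = n_groups * p (p - 1) / 2`. Values of 0.90 and 0.95 are the usual
#' thresholds for acceptable and good fit.
#'
#' @param fit A `sem_fit`.
#' @param baseline Optional `sem_fit` to use as the baseline model.
#' @return A tibble with `chisq`, `df`, `p.value`, `baseline_chisq`,
#'   `baseline_df`, `cfi`.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  if (is.null(baseline)) {
    Tb <- 0; dfb <- 0L
    for (g in seq_len(fit$ngroups)) {
      S <- fit$moments[[g]]$cov
      p <- nrow(S)
      Fb <- sum(log(diag(S))) - 2 * sum(log(diag(chol(S))))
      Tb <- Tb + fit$weights[g] * Fb
      dfb <- dfb + as.integer(p * (p - 1) / 2)
    }
  } else {
    stopifnot(inherits(baseline, "sem_fit"))
    Tb <- baseline$chisq
    dfb <- baseline$df
  }
  num <- max(fit$chisq - fit$df, 0)
  den <- max(Tb - dfb, fit$chisq - fit$df, 0)
  if (Tb <= dfb) {
    warning("baseline chi-square does not exceed its df; CFI reported as 1",
            call. = FALSE)
  }
  cfi <- if (den <= 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  tibble::tibble(chisq = fit$chisq, df = fit$df, p.value = fit$pvalue,
                 baseline_chisq = Tb, baseline_df = dfb, cfi = cfi)
}

#' Chi-square difference test for nested models
#'
#' Compares a nested (more constrained) model against a full model fitted to
#' the same data: `delta_chisq = T_nested - T_full` referred to a chi-square
#' distribution with `delta_df = df_nested - df_full`. This is the likelihood
#' ratio ("ANOVA") comparison commonly used to decide whether an extra path
#' improves a model.
#'
#' @param nested The constrained `sem_fit` (larger df).
#' @param full The less constrained `sem_fit`.
#' @return A tibble with `delta_chisq`, `delta_df`, `p.value`.
#' @export
chisq_diff_test <- function(nested, full) {
  stopifnot(inherits(nested, "sem_fit"), inherits(full, "sem_fit"))
  same_vars <- identical(sort(nested$var_order[nested$obs_idx]),
                         sort(full$var_order[full$obs_idx]))
  same_data <- same_vars && nested$ngroups == full$ngroups &&
    isTRUE(all.equal(
      lapply(nested$moments, function(m) m$cov[order(rownames(m$cov)),
                                               order(rownames(m$cov))]),
      lapply(full$moments, function(m) m$cov[order(rownames(m$cov)),
                                             order(rownames(m$cov))]),
      check.attributes = FALSE))
  if (!same_data) stop("models were fitted to different data", call. = FALSE)
  if (nested$df == full$df) stop("models have equal df; not nested", call. = FALSE)
  if (nested$df < full$df) stop("'nested' must have more df than 'full'",
                                call. = FALSE)
  dchisq <- nested$chisq - full$chisq
  ddf <- nested$df - full$df
  if (dchisq < -1e-6) {
    warning("nested model fits better than the full model (delta chi-square ",
            signif(dchisq, 4), "); check convergence", call. = FALSE)
  }
  dchisq <- max(dchisq, 0)
  tibble::tibble(delta_chisq = dchisq, delta_df = ddf,
                 p.value = stats::pchisq(dchisq, ddf, lower.tail = FALSE))
}

#' @export
anova.sem_fit <- function(object, ..., test = TRUE) {
  others <- list(...)
  others <- others[vapply(others, inherits, logical(1), "sem_fit")]
  if (length(others) != 1L) {
    stop("anova() on a sem_fit needs exactly one other sem_fit", call. = FALSE)
  }
  pair <- list(object, others[[1]])
  dfs <- vapply(pair, function(f) f$df, numeric(1))
  nested <- pair[[which.max(dfs)]]
  full <- pair[[which.min(dfs)]]
  chisq_diff_test(nested, full)
}
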