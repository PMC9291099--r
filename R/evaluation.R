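#' Bias and precision of a vector of estimates
#'
#' Mean bias `B = mean(theta_hat_i) - theta`, empirical standard error
#' `E = sd(theta_hat_i)` (the `nsim - 1` denominator), and the relative bias
#' `100 * B / theta` in percent — reported `NA` when the true value is close
#' to zero (`|theta| < rel_threshold`), where a percentage of almost-nothing
#' is not meaningful.
#'
#' @param estimates Numeric vector of replicate estimates (length >= 2).
#' @param true_value The generating parameter value.
#' @param rel_threshold Magnitude below which relative bias is suppressed
#'   (default 0.05).
#' @return A one-row tibble with `bias`, `empirical_se`, `relative_bias`.
#' @export
bias_metrics <- function(estimates, true_value, rel_threshold = 0.05) {
  estimates <- unname(as.numeric(estimates))
  true_value <- unname(true_value)
  if (length(estimates) < 2L) {
    stop("need at least 2 estimates for the empirical standard error",
         call. = FALSE)
  }
  bias <- mean(estimates) - true_value
  emp_se <- stats::sd(estimates)
  rel <- if (abs(true_value) < rel_threshold) NA_real_ else 100 * bias / true_value
  tibble::tibble(bias = bias, empirical_se = emp_se, relative_bias = rel)
}

# condition-variable total effects on the survival outcome implied by a
# fitted/true parameter table: weight * (outcome ~ composite) slope
composite_total_effects <- function(ptab, group = 1L) {
  pt <- ptab[ptab$group == group, ]
  comp_rows <- pt[pt$op == "<~", ]
  if (nrow(comp_rows) == 0L) stop("model has no composite", call. = FALSE)
  comp <- comp_rows$lhs[1]
  out_row <- pt[pt$op == "~" & pt$rhs == comp, ]
  out_row <- out_row[!(out_row$lhs %in% c(comp)), ]
  if (nrow(out_row) == 0L) stop("no outcome regressed on the composite",
                                call. = FALSE)
  b <- out_row$estimate[1]
  stats::setNames(comp_rows$estimate * b, comp_rows$rhs)
}

#' Monte-Carlo bias experiment: joint SEM versus stepwise estimation
#'
#' Simulates `nsim` datasets of `n` rows from a true model, estimates the
#' effect of each condition variable on survival with each method, and
#' summarises per-parameter bias and empirical standard error. For the SEM the
#' estimate is the fitted composite weight times the composite-to-survival
#' slope (the total effect); for the stepwise baseline it is the step-2
#' multiple-regression slope, with residual body mass standing in for the
#' size-corrected-mass latent. Non-converged replicates are excluded and
#' counted; more than 10\% of them aborts the run.
#'
#' @param tm A `sem_true_model` with a composite condition structure, e.g.
#'   `condition_fixture("condition")`.
#' @param nsim Number of simulated datasets (>= 2).
#' @param n Rows per dataset.
#' @param seed Integer seed; replicate `i` uses an internal substream.
#' @param methods Subset of `c("sem", "stepwise")`.
#' @param rel_threshold Passed to [bias_metrics()].
#' @return A `bias_sim` object; `tidy()` gives the per-parameter table with
#'   `method`, `parameter`, `true_value`, `mean_estimate`, `bias`,
#'   `empirical_se`, `relative_bias`.
#' @export
run_bias_experiment <- function(tm, nsim = 200L, n = 1000L, seed = 1L,
                                methods = c("sem", "stepwise"),
                                rel_threshold = 0.05) {
  stopifnot(inherits(tm, "sem_true_model"), nsim >= 2L)
  methods <- match.arg(methods, several.ok = TRUE)
  true_eff <- composite_total_effects(tm$ptab)
  params <- names(true_eff)
  est <- list()
  for (m0 in methods) {
    est[[m0]] <- matrix(NA_real_, nsim, length(params),
                        dimnames = list(NULL, params))
  }
  nonconv <- stats::setNames(integer(length(methods)), methods)
  for (i in seq_len(nsim)) {
    d <- simulate_from(tm, n, substream_seed(seed, i))
    if ("sem" %in% methods) {
      f <- tryCatch(suppressWarnings(sem_fit(d, tm$model, se = FALSE)),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) {
        nonconv[["sem"]] <- nonconv[["sem"]] + 1L
      } else {
        est[["sem"]][i, ] <- composite_total_effects(f$ptab)[params]
      }
    }
    if ("stepwise" %in% methods) {
      s <- tryCatch(stepwise_condition_index(d), error = function(e) NULL)
      if (is.null(s)) {
        nonconv[["stepwise"]] <- nonconv[["stepwise"]] + 1L
      } else {
        co <- s$step2_coefficients
        sl <- stats::setNames(co$estimate, co$term)
        names(sl)[names(sl) == "resid_mass"] <- "size_corrected_mass"
        est[["stepwise"]][i, ] <- sl[params]
      }
    }
  }
  for (m0 in methods) {
    rate <- nonconv[[m0]] / nsim
    if (rate > 0.10) {
      stop(sprintf("method '%s' failed on %.0f%% of replicates (limit 10%%)",
                   m0, 100 * rate), call. = FALSE)
    }
    if (nonconv[[m0]] > 0L) {
      message(sprintf("method '%s': %d/%d replicate(s) excluded (non-converged)",
                      m0, nonconv[[m0]], nsim))
    }
  }
  results <- dplyr::bind_rows(lapply(methods, function(m0) {
    dplyr::bind_rows(lapply(params, function(p0) {
      e <- est[[m0]][, p0]
      e <- e[!is.na(e)]
      dplyr::bind_cols(
        tibble::tibble(method = m0, parameter = p0,
                       true_value = unname(true_eff[p0]),
                       mean_estimate = mean(e), n_used = length(e)),
        bias_metrics(e, true_eff[p0], rel_threshold))
    }))
  }))
  structure(list(results = results, estimates = est, nsim = nsim, n = n,
                 seed = seed, nonconverged = nonconv,
                 rel_threshold = rel_threshold),
            class = "bias_sim")
}

#' @export
print.bias_sim <- function(x, ...) {
  cat(sprintf("<bias_sim> nsim = %d, n = %d, seed = %d\n", x$nsim, x$n, x$seed))
  print(x$results)
  invisible(x)
}

#' @method tidy bias_sim
#' @export
tidy.bias_sim <- function(x, ...) x$results

#' Repeated k-fold cross-validation of the two condition-index pipelines
#'
#' Per repeat, rows are randomly partitioned into `folds` folds; per fold,
#' both methods are fitted on the training portion and predict survival on
#' the held-out portion. The SEM form of the model excludes density (the aim
#' is out-of-sample survival prediction from the condition variables); its
#' prediction applies the fitted composite weights and the
#' condition-to-survival path to the test rows, centred at the training
#' means. The conventional prediction applies the step-1 and step-2
#' regressions. RMSE and R-squared (`1 - SSE/SST`, possibly negative) are
#' computed over pooled out-of-fold predictions by default.
#'
#' @param data A data frame with the condition-model columns.
#' @param map Role-to-column mapping as in [condition_model()].
#' @param folds Number of folds (>= 2); `folds = nrow(data)` gives
#'   leave-one-out.
#' @param repeats Number of random re-partitions; `folds * repeats` training
#'   and test sets in total.
#' @param seed Integer seed for fold assignment.
#' @param method `"kfold"` (default) or `"mc_split"` for `folds * repeats`
#'   Monte-Carlo train/test splits of proportion `train_frac`.
#' @param train_frac Training proportion for `mc_split` (default 0.8).
#' @param logit_survival Logit-transform the survival column first?
#' @param r2_mode `"pooled"` (default) or `"per_fold"` (average of per-fold
#'   statistics).
#' @return A `cond_cv` object; `tidy()` gives per-method `rmse`, `r_squared`,
#'   `n_fits`, `n_skipped`.
#' @export
cross_validate <- function(data, map = NULL, folds = 10L, repeats = 3L,
                           seed = 1L, method = c("kfold", "mc_split"),
                           train_frac = 0.8, logit_survival = FALSE,
                           r2_mode = c("pooled", "per_fold")) {
  method <- match.arg(method)
  r2_mode <- match.arg(r2_mode)
  stopifnot(folds >= 2L, repeats >= 1L)
  data <- tibble::as_tibble(data)
  v <- function(role) {
    if (!is.null(map) && role %in% names(map)) unname(map[[role]]) else role
  }
  phys <- vapply(c("buffy_coat", "haematocrit", "cholesterol", "uric_acid",
                   "corticosterone"), v, character(1))
  need <- c(v("mass"), v("tarsus"), v("head"), v("wing"), phys, v("survival"))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  data <- data[stats::complete.cases(data[need]), ]
  n <- nrow(data)
  if (n < folds) stop("fewer rows than folds", call. = FALSE)
  if (logit_survival) data[[v("survival")]] <- stats::qlogis(data[[v("survival")]])
  sem_model0 <- condition_model("condition_composite", map = map,
                                include_density = FALSE)
  npar_sem <- sum(is.na(sem_model0$terms$fixed))
  preds <- list()
  n_skipped <- c(sem = 0L, conventional = 0L)
  for (r in seq_len(repeats)) {
    set.seed(substream_seed(seed, r))
    assign_f <- if (method == "kfold") {
      sample(rep_len(seq_len(folds), n))
    } else {
      NULL
    }
    for (k in seq_len(folds)) {
      if (method == "kfold") {
        test_idx <- which(assign_f == k)
      } else {
        test_idx <- sample(n, size = max(1L, round((1 - train_frac) * n)))
      }
      train <- data[-test_idx, ]
      test <- data[test_idx, ]
      if (nrow(train) <= npar_sem) {
        stop("training fold has ", nrow(train), " rows for ", npar_sem,
             " free parameters; use fewer folds", call. = FALSE)
      }
      obs <- test[[v("survival")]]
      # SEM route
      f <- tryCatch(suppressWarnings(sem_fit(train, sem_model0, se = FALSE)),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) {
        n_skipped[["sem"]] <- n_skipped[["sem"]] + 1L
      } else {
        sc <- suppressWarnings(sem_scores(f, test))
        pt <- f$ptab
        b <- pt$estimate[pt$op == "~" & pt$rhs == "condition" &
                           pt$lhs == v("survival")]
        ybar <- f$moments[[1]]$means[[v("survival")]]
        pred <- ybar + b * sc$condition
        preds[[length(preds) + 1L]] <- tibble::tibble(
          method = "sem", rep = r, fold = k, .row = test_idx,
          obs = obs, pred = pred)
      }
      # conventional route
      s <- tryCatch(stepwise_condition_index(train, map = map),
                    error = function(e) NULL)
      if (is.null(s)) {
        n_skipped[["conventional"]] <- n_skipped[["conventional"]] + 1L
      } else {
        test2 <- test
        test2$resid_mass <- test2[[v("mass")]] -
          as.numeric(stats::predict(s$step1_fit, newdata = test2))
        pred <- as.numeric(stats::predict(s$step2_fit, newdata = test2))
        preds[[length(preds) + 1L]] <- tibble::tibble(
          method = "conventional", rep = r, fold = k, .row = test_idx,
          obs = obs, pred = pred)
      }
    }
  }
  total_fits <- folds * repeats
  for (m0 in names(n_skipped)) {
    if (n_skipped[[m0]] / total_fits > 0.10) {
      stop(sprintf("method '%s' failed on %d of %d folds (limit 10%%)",
                   m0, n_skipped[[m0]], total_fits), call. = FALSE)
    }
  }
  preds <- dplyr::bind_rows(preds)
  summarise_one <- function(d) {
    if (r2_mode == "pooled") {
      sse <- sum((d$obs - d$pred)^2)
      sst <- sum((d$obs - mean(d$obs))^2)
      tibble::tibble(rmse = sqrt(mean((d$obs - d$pred)^2)),
                     r_squared = 1 - sse / sst)
    } else {
      per <- d |>
        dplyr::group_by(rep, fold) |>
        dplyr::summarise(rmse = sqrt(mean((obs - pred)^2)),
                         r2 = 1 - sum((obs - pred)^2) /
                           sum((obs - mean(obs))^2), .groups = "drop")
      tibble::tibble(rmse = mean(per$rmse), r_squared = mean(per$r2))
    }
  }
  summary <- preds |>
    dplyr::group_by(method) |>
    dplyr::group_modify(~ summarise_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(n_fits = total_fits - n_skipped[method],
                  n_skipped = n_skipped[method])
  structure(list(summary = summary, predictions = preds, folds = folds,
                 repeats = repeats, seed = seed, method = method,
                 r2_mode = r2_mode, n = n),
            class = "cond_cv")
}

#' @export
print.cond_cv <- function(x, ...) {
  cat(sprintf("<cond_cv> %d x %d-fold (%s), n = %d\n", x$repeats, x$folds,
              x$method, x$n))
  print(x$summary)
  invisible(x)
}

#' @method tidy cond_cv
#' @export
tidy.cond_cv <- function(x, ...) x$summary
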