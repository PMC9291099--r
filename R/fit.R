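#' Fit a structural equation model by maximum likelihood
#'
#' Estimates a covariance-structure model (latent, composite and observed
#' variables) by classical Wishart maximum likelihood on the (N-1)-denominator
#' sample covariance. Multi-group models minimise the sum of per-group
#' `(N_g - 1) * F_ML`, which is also the reported chi-square. Rows with
#' missing values on model variables are listwise-deleted and the retained N
#' recorded. The fit is deterministic given data and model.
#'
#' @param data A data frame with one row per individual. Alternatively `NULL`
#'   when `sample_cov`/`sample_nobs` are supplied.
#' @param model A `sem_model` (raw models are identified automatically via
#'   [apply_identification()]).
#' @param group Optional name of a grouping column; overrides `model$groups`.
#' @param sample_cov A covariance matrix (or list of matrices, one per group)
#'   with dimnames, used instead of raw data.
#' @param sample_nobs Observation count(s) matching `sample_cov`.
#' @param se Compute standard errors from the inverse observed information of
#'   the `(N-1) F_ML / 2`-scaled objective? Default `TRUE`.
#' @param std_lv Passed to [apply_identification()].
#' @param chisq_scale `"n-1"` (Wishart, default) or `"n"` scaling of the
#'   chi-square weights.
#' @param control Passed to [stats::nlminb()] (defaults: `iter.max = 10000`,
#'   `eval.max = 20000`, `rel.tol = 1e-10`).
#' @return A `sem_fit` object; see [tidy.sem_fit()] and [glance.sem_fit()].
#' @examples
#' d <- simulate_from(condition_fixture("energy"), n = 500, seed = 1)
#' f <- sem_fit(d, condition_model("energy_cfa"))
#' glance(f)
#' @export
sem_fit <- function(data, model, group = NULL, sample_cov = NULL,
                    sample_nobs = NULL, se = TRUE, std_lv = FALSE,
                    chisq_scale = c("n-1", "n"), control = list()) {
  chisq_scale <- match.arg(chisq_scale)
  stopifnot(inherits(model, "sem_model"))
  if (!model$identified) model <- apply_identification(model, std_lv = std_lv)
  if (!is.null(group)) model$groups <- group

  obs <- observed_vars(model)
  n_dropped <- 0L
  if (!is.null(sample_cov)) {
    if (is.matrix(sample_cov)) sample_cov <- list(sample_cov)
    stopifnot(length(sample_nobs) == length(sample_cov))
    moments <- purrr::map2(sample_cov, sample_nobs, function(cv, n) {
      miss <- setdiff(obs, rownames(cv))
      if (length(miss)) stop("covariance matrix lacks variables: ",
                             paste(miss, collapse = ", "), call. = FALSE)
      sem_moments(cv[obs, obs, drop = FALSE], n)
    })
    group_labels <- names(sample_cov) %||% as.character(seq_along(sample_cov))
  } else {
    data <- tibble::as_tibble(data)
    miss <- setdiff(obs, names(data))
    if (length(miss)) stop("model variables not present in data: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    need <- c(obs, model$groups)
    keep <- stats::complete.cases(data[need])
    n_dropped <- sum(!keep)
    data <- data[keep, need]
    if (!is.null(model$groups)) {
      split_data <- split(data[obs], data[[model$groups]])
      group_labels <- names(split_data)
    } else {
      split_data <- list(data[obs])
      group_labels <- "all"
    }
    moments <- purrr::map(split_data, function(d) {
      if (nrow(d) <= length(obs)) {
        stop("group with N = ", nrow(d), " <= p = ", length(obs), call. = FALSE)
      }
      sem_moments(stats::cov(as.matrix(d)), nrow(d),
                  means = colMeans(as.matrix(d)))
    })
  }
  ng <- length(moments)
  N <- sum(vapply(moments, function(m) m$n, integer(1)))
  weights <- vapply(moments, function(m)
    if (chisq_scale == "n-1") m$n - 1 else m$n, numeric(1))

  var_order <- model_var_order(model, obs)
  ptab <- build_param_table(model, group_labels, moments)
  skels <- lapply(seq_len(ng), function(g)
    ram_skeleton(ptab[ptab$group == g, ], var_order))
  obs_idx <- seq_along(obs)
  objective <- make_objective(skels, moments, obs_idx, weights)

  df <- model_df(model, p = length(obs), n_groups = ng)

  # lower bounds: variances at 1e-10, everything else unbounded
  theta0 <- numeric(objective$npar)
  lower <- rep(-Inf, objective$npar)
  free <- ptab$free
  theta0[ptab$par[free]] <- ptab$start[free]
  is_var <- ptab$op == "~~" & ptab$lhs == ptab$rhs
  lower[ptab$par[free & is_var]] <- 1e-10

  ctrl <- utils::modifyList(list(iter.max = 10000L, eval.max = 20000L,
                                 rel.tol = 1e-10), control)
  opt <- stats::nlminb(theta0, objective$fn, gradient = objective$gr,
                       lower = lower, control = ctrl)
  # convergence criterion on the per-observation (F_ML) scale: the objective
  # is sum_g w_g F_g, so divide the gradient norm by the total weight. At an
  # active lower bound (a Heywood boundary solution) only the infeasible
  # descent direction counts (KKT projection).
  gtol <- 1e-6 * max(1, sum(weights))
  kkt_norm <- function(par) {
    g <- objective$gr(par)
    at_bound <- par <= lower + 1e-9
    max(ifelse(at_bound, pmax(-g, 0), abs(g)), 0)
  }
  gnorm <- kkt_norm(opt$par)
  restarts <- 0L
  while (gnorm > gtol && restarts < 4L) {
    # alternate plain and parameter-scaled restarts: rescaling rescues the
    # ill-conditioned weight/slope valley of near-null composite models
    scale <- if (restarts %% 2L == 0L) 1 / pmax(abs(opt$par), 1e-2) else 1
    opt2 <- stats::nlminb(opt$par, objective$fn, gradient = objective$gr,
                          scale = scale, lower = lower, control = ctrl)
    if (opt2$objective <= opt$objective) opt <- opt2
    gnorm <- kkt_norm(opt$par)
    restarts <- restarts + 1L
  }
  theta <- opt$par
  converged <- gnorm <= gtol || opt$convergence == 0
  boundary <- theta <= lower + 1e-9
  if (converged && any(boundary)) {
    pv <- ptab[ptab$free, ]
    pv <- pv[order(pv$par), ]
    at <- unique(paste(pv$lhs[boundary[pv$par]], "~~", pv$rhs[boundary[pv$par]]))
    warning("variance estimate(s) at the lower bound (Heywood case): ",
            paste(at, collapse = ", "), call. = FALSE)
  }
  if (!converged) {
    warning("optimizer did not converge (gradient max-norm ", signif(gnorm, 3),
            " after ", opt$iterations, " iterations)", call. = FALSE)
  }

  ptab$estimate <- ifelse(free, theta[pmax(ptab$par, 1L)], ptab$fixed)
  ptab$group_label <- group_labels[ptab$group]

  chisq <- max(opt$objective, 0)
  fml_g <- objective$fml(theta)
  fit <- structure(list(
    model = model, ptab = ptab, moments = moments, var_order = var_order,
    obs_idx = obs_idx, skels = skels, weights = weights,
    fml = sum(fml_g), fml_by_group = fml_g,
    chisq = chisq, df = df,
    pvalue = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    converged = converged, gradient_norm = gnorm, iterations = opt$iterations,
    nobs = N, n_dropped = n_dropped, ngroups = ng, group_labels = group_labels,
    chisq_scale = chisq_scale, theta = theta, objective = objective,
    vcov = NULL
  ), class = "sem_fit")
  fit$ptab$se <- NA_real_
  fit$ptab$z <- NA_real_
  fit$ptab$p.value <- NA_real_
  fit$ptab$std_estimate <- NA_real_
  if (converged) {
    if (se) fit <- standard_errors(fit)
    fit <- standardized_solution(fit)
  }
  fit
}

#' Wald standard errors for a fitted model
#'
#' Fills the `se`, `z` and `p.value` columns of the parameter table with
#' standard errors from the inverse observed information of the
#' `(N-1) F_ML / 2`-scaled objective, Wald z statistics, and two-sided normal
#' p-values. A singular information matrix yields per-parameter `NA` with a
#' warning rather than failure.
#'
#' @param fit A converged `sem_fit`.
#' @return The `sem_fit` with the uncertainty columns filled.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("cannot compute standard errors: fit did not converge",
                           call. = FALSE)
  half_fn <- function(th) 0.5 * fit$objective$fn(th)
  half_gr <- function(th) 0.5 * fit$objective$gr(th)
  H <- stats::optimHess(fit$theta, half_fn, half_gr)
  V <- tryCatch(solve(H), error = function(e) NULL)
  npar <- length(fit$theta)
  ses <- rep(NA_real_, npar)
  if (is.null(V) || any(!is.finite(diag(V)))) {
    warning("observed information is singular; standard errors reported as NA",
            call. = FALSE)
  } else {
    dg <- diag(V)
    neg <- dg < 0
    if (any(neg)) {
      warning("negative information diagonal for ", sum(neg),
              " parameter(s); their standard errors reported as NA", call. = FALSE)
      dg[neg] <- NA_real_
    }
    ses <- sqrt(dg)
    fit$vcov <- V
  }
  fit$ptab$se <- ifelse(fit$ptab$free, ses[pmax(fit$ptab$par, 1L)], NA_real_)
  fit$ptab$z <- fit$ptab$estimate / fit$ptab$se
  fit$ptab$p.value <- 2 * stats::pnorm(abs(fit$ptab$z), lower.tail = FALSE)
  fit
}

# Full t x t implied covariance of one group at the estimates.
full_implied_cov <- function(fit, g = 1L) {
  skel <- fit$skels[[g]]
  ram <- ram_matrices(skel, fit$theta)
  t_n <- skel$t_n
  B <- solve(diag(t_n) - ram$A)
  V <- B %*% ram$S %*% t(B)
  dimnames(V) <- list(fit$var_order, fit$var_order)
  list(V = (V + t(V)) / 2, A = ram$A, S = ram$S, B = B)
}

#' Standardized solution
#'
#' Fills `std_estimate`: every directed coefficient b(x -> y) is reported as
#' `b * sd(x) / sd(y)` with model-implied standard deviations (latent and
#' composite variances taken from the implied covariance of the full system);
#' covariances become correlations and variances are rescaled by the implied
#' variance of their variable (so the variance of a standardized exogenous
#' latent is 1).
#'
#' @param fit A converged `sem_fit`.
#' @return The `sem_fit` with `std_estimate` filled.
#' @export
standardized_solution <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("cannot standardize a non-converged fit", call. = FALSE)
  std <- rep(NA_real_, nrow(fit$ptab))
  for (g in seq_len(fit$ngroups)) {
    V <- full_implied_cov(fit, g)$V
    sdv <- sqrt(pmax(diag(V), 0))
    if (any(sdv <= 0)) {
      bad <- fit$var_order[sdv <= 0][1]
      stop("implied variance of '", bad, "' is zero; cannot standardize",
           call. = FALSE)
    }
    names(sdv) <- fit$var_order
    rows <- which(fit$ptab$group == g)
    for (r in rows) {
      op <- fit$ptab$op[r]; lhs <- fit$ptab$lhs[r]; rhs <- fit$ptab$rhs[r]
      b <- fit$ptab$estimate[r]
      std[r] <- switch(op,
        "=~" = b * sdv[[lhs]] / sdv[[rhs]],   # latent -> indicator
        "~"  = b * sdv[[rhs]] / sdv[[lhs]],
        "<~" = b * sdv[[rhs]] / sdv[[lhs]],   # cause -> composite
        "~~" = if (lhs == rhs) b / (sdv[[lhs]]^2) else b / (sdv[[lhs]] * sdv[[rhs]]))
    }
  }
  fit$ptab$std_estimate <- std
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit> ", if (x$converged) "converged" else "NOT converged",
      sprintf("; N = %d (%d dropped), groups = %d\n", x$nobs, x$n_dropped, x$ngroups))
  cat(sprintf("  chisq = %.3f on df = %d%s\n", x$chisq, x$df,
              if (!is.na(x$pvalue)) sprintf(" (p = %.3g)", x$pvalue) else ""))
  invisible(x)
}

#' Tidy a fitted SEM
#'
#' One row per parameter: `lhs`, `op`, `rhs`, `group`, `free`, `estimate`,
#' `se`, `z`, `p.value`, `std_estimate`.
#'
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sem_fit
#' @export
tidy.sem_fit <- function(x, ...) {
  cols <- c("lhs", "op", "rhs", "group_label", "free", "fixed", "estimate",
            "se", "z", "p.value", "std_estimate")
  out <- x$ptab
  for (c0 in c("se", "z", "p.value", "std_estimate")) {
    if (is.null(out[[c0]])) out[[c0]] <- NA_real_
  }
  out <- out[cols]
  names(out)[names(out) == "group_label"] <- "group"
  tibble::as_tibble(out)
}

#' Glance at a fitted SEM
#'
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `chisq`, `df`, `p.value`, `cfi`, `fml`,
#'   `nobs`, `n_dropped`, `ngroups`, `converged`.
#' @method glance sem_fit
#' @export
glance.sem_fit <- function(x, ...) {
  fi <- fit_indices(x)
  tibble::tibble(chisq = x$chisq, df = x$df, p.value = x$pvalue, cfi = fi$cfi,
                 fml = x$fml, nobs = x$nobs, n_dropped = x$n_dropped,
                 ngroups = x$ngroups, converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

`%||%` <- function(a, b) if (is.null(a)) b else a
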