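#' Principal component analysis for condition variables
#'
#' Eigen-decomposition of the correlation (default) or covariance matrix of
#' the selected variables, the conventional variable-reduction step for
#' condition indices. Components are ordered by variance explained and each
#' component is sign-flipped so its largest-magnitude loading is positive
#' (loadings are only defined up to sign, so this fixes a convention).
#'
#' @param data A data frame.
#' @param variables Character vector of (>= 2) column names.
#' @param standardize Use the correlation matrix (`TRUE`, default; sensible
#'   when variables mix units) or the covariance matrix.
#' @return A `cond_pca` object with elements `loadings` (variable x component
#'   matrix), `variance_explained` (proportions summing to 1), `scores`
#'   (row x component, `NA` for incomplete rows), `n`.
#' @export
principal_components <- function(data, variables, standardize = TRUE) {
  stopifnot(length(variables) >= 2L)
  data <- tibble::as_tibble(data)
  miss <- setdiff(variables, names(data))
  if (length(miss)) stop("variables not in data: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  X <- as.matrix(data[variables])
  complete <- stats::complete.cases(X)
  Xc <- X[complete, , drop = FALSE]
  vars <- apply(Xc, 2, stats::var)
  if (any(vars == 0)) {
    stop("constant column: ", paste(variables[vars == 0], collapse = ", "),
         call. = FALSE)
  }
  C <- if (standardize) stats::cor(Xc) else stats::cov(Xc)
  ee <- eigen(C, symmetric = TRUE)
  L <- ee$vectors
  for (k in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, k])), k] < 0) L[, k] <- -L[, k]
  }
  dimnames(L) <- list(variables, paste0("PC", seq_len(ncol(L))))
  center <- colMeans(Xc)
  scale_ <- if (standardize) sqrt(vars) else rep(1, length(vars))
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")
  scores <- Z %*% L
  structure(list(loadings = L,
                 variance_explained = ee$values / sum(ee$values),
                 scores = scores, center = center, scale = scale_,
                 standardize = standardize, variables = variables,
                 n = sum(complete)),
            class = "cond_pca")
}

#' @export
print.cond_pca <- function(x, ...) {
  cat("<cond_pca>", length(x$variables), "variables, n =", x$n, "\n")
  cat("  PC1 explains", sprintf("%.1f%%", 100 * x$variance_explained[1]), "\n")
  invisible(x)
}

#' @method tidy cond_pca
#' @export
tidy.cond_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @method glance cond_pca
#' @export
glance.cond_pca <- function(x, ...) {
  tibble::tibble(component = colnames(x$loadings),
                 variance_explained = x$variance_explained,
                 n = x$n)
}

#' Residuals from an auxiliary least-squares regression
#'
#' Ordinary least squares of `response` on `predictors`; the returned data
#' gains a `.resid` column (`NA` on incomplete rows). This is the
#' residual-body-mass step of the conventional condition index: regress mass
#' on the structural sizes and keep what size cannot explain.
#'
#' @param data A data frame.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return `data` with an added `.resid` column.
#' @export
residual_regression <- function(data, response, predictors) {
  data <- tibble::as_tibble(data)
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = data, na.action = stats::na.exclude)
  if (fit$rank < length(predictors) + 1L) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  data$.resid <- as.numeric(stats::residuals(fit))
  attr(data, "resid_fit") <- fit
  data
}

#' Four-step conventional condition index
#'
#' The stepwise multiple-regression / residual-analysis baseline:
#'
#' 1. regress mass on the three structural sizes and keep the residuals
#'    (residual body mass);
#' 2. regress survival on residual mass plus the five physiological
#'    variables;
#' 3. the fitted values of step 2 are the body-condition index;
#' 4. regress the index on competitor density.
#'
#' Because later steps consume residuals/predictions of earlier ones, the
#' procedure can yield biased slope estimates when the variables involved are
#' not mutually uncorrelated — the motivation for the joint SEM alternative.
#' The pipeline is deterministic given the dataset.
#'
#' @param data A data frame.
#' @param map Role-to-column mapping as in [condition_model()].
#' @param logit_survival Apply a logit transform to the survival column first?
#' @return A `stepwise_index` object with `rows` (tibble of `.row`,
#'   `resid_mass`, `index`), `step2_coefficients`, `step4_density_slope`,
#'   `step2_fit`, `n`.
#' @export
stepwise_condition_index <- function(data, map = NULL, logit_survival = FALSE) {
  data <- tibble::as_tibble(data)
  v <- function(role) {
    if (!is.null(map) && role %in% names(map)) unname(map[[role]]) else role
  }
  phys <- vapply(c("buffy_coat", "haematocrit", "cholesterol", "uric_acid",
                   "corticosterone"), v, character(1))
  need <- c(v("mass"), v("tarsus"), v("head"), v("wing"), phys, v("survival"),
            v("density"))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (logit_survival) data[[v("survival")]] <- stats::qlogis(data[[v("survival")]])
  # step 1: residual body mass
  step1 <- residual_regression(data, v("mass"), c(v("tarsus"), v("head"), v("wing")))
  data$resid_mass <- step1$.resid
  # step 2: survival on residual mass + physiology
  f2 <- stats::reformulate(c("resid_mass", phys), v("survival"))
  step2 <- stats::lm(f2, data = data, na.action = stats::na.exclude)
  coefs <- summary(step2)$coefficients
  step2_coefficients <- tibble::tibble(
    term = rownames(coefs), estimate = coefs[, 1], se = coefs[, 2],
    statistic = coefs[, 3], p.value = coefs[, 4])
  # step 3: fitted values are the condition index
  data$index <- as.numeric(stats::predict(step2, newdata = data))
  # step 4: index on density
  f4 <- stats::reformulate(v("density"), "index")
  step4 <- stats::lm(f4, data = data, na.action = stats::na.exclude)
  structure(list(
    rows = tibble::tibble(.row = seq_len(nrow(data)),
                          resid_mass = data$resid_mass, index = data$index),
    step2_coefficients = step2_coefficients,
    step4_density_slope = unname(stats::coef(step4)[v("density")]),
    step1_fit = attr(step1, "resid_fit"), step2_fit = step2, step4_fit = step4,
    map = map, n = sum(stats::complete.cases(data[need]))),
    class = "stepwise_index")
}

#' @export
print.stepwise_index <- function(x, ...) {
  cat("<stepwise_index> n =", x$n, "\n")
  cat("  step-4 density slope:", signif(x$step4_density_slope, 4), "\n")
  invisible(x)
}

#' @method tidy stepwise_index
#' @export
tidy.stepwise_index <- function(x, ...) x$step2_coefficients
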