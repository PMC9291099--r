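#' Attach true parameter values to a model
#'
#' Pairs an identified `sem_model` with the generating ("true") values of all
#' its free parameters, yielding an object that can be simulated from. Values
#' are keyed `"lhs op rhs"` (e.g. `"energy =~ ratio"`, `"survival ~
#' condition"`, `"mass ~~ mass"`); covariance keys are order-insensitive. For
#' multi-group models supply a named list of value vectors, one per group
#' label.
#'
#' @param model A `sem_model` (identified automatically if raw).
#' @param values Named numeric vector of true values for every free parameter,
#'   or a named list of such vectors for multi-group models.
#' @param group_labels Group labels for multi-group models; defaults to
#'   `names(values)`.
#' @return A `sem_true_model` with the cached implied covariance per group
#'   (checked positive definite).
#' @export
sem_true_model <- function(model, values, group_labels = NULL) {
  stopifnot(inherits(model, "sem_model"))
  if (!model$identified) model <- apply_identification(model)
  if (!is.list(values)) values <- list(all = values)
  if (is.null(group_labels)) group_labels <- names(values)
  ng <- length(values)
  obs <- observed_vars(model)
  var_order <- model_var_order(model, obs)
  empty <- matrix(numeric(0), 0, 0)
  moments <- rep(list(list(cov = `dimnames<-`(diag(0), list(NULL, NULL)))), ng)
  ptab <- build_param_table(model, group_labels, moments)
  key <- paste(ptab$lhs, ptab$op, ptab$rhs)
  for (g in seq_len(ng)) {
    vals <- values[[g]]
    nm <- names(vals)
    # canonicalize '~~' keys order-insensitively
    nm <- vapply(strsplit(nm, "\\s+"), function(b) {
      if (length(b) == 3L && b[2] == "~~") {
        paste(min(b[1], b[3]), "~~", max(b[1], b[3]))
      } else paste(b, collapse = " ")
    }, character(1))
    rows <- which(ptab$group == g & ptab$free)
    hit <- match(key[rows], nm)
    if (anyNA(hit)) {
      stop("missing true value for free parameter(s): ",
           paste(utils::head(key[rows][is.na(hit)], 5L), collapse = "; "),
           if (sum(is.na(hit)) > 5L) " ..." else "",
           " (group ", group_labels[g], ")", call. = FALSE)
    }
    extra <- setdiff(nm, key[rows])
    if (length(extra)) {
      stop("true values given for unknown or fixed parameter(s): ",
           paste(extra, collapse = "; "), call. = FALSE)
    }
    ptab$estimate[rows] <- as.numeric(vals)[hit]
  }
  skels <- lapply(seq_len(ng), function(g) ram_skeleton(ptab[ptab$group == g, ],
                                                        var_order))
  implied <- lapply(seq_len(ng), function(g) {
    pt <- ptab[ptab$group == g, ]
    theta <- numeric(max(pt$par, 1L))
    theta[pt$par[pt$free]] <- pt$estimate[pt$free]
    ram <- ram_matrices(skels[[g]], theta)
    Sigma <- implied_covariance(ram$A, ram$S, seq_along(obs))
    dimnames(Sigma) <- list(obs, obs)
    ok <- tryCatch({ chol(Sigma); TRUE }, error = function(e) FALSE)
    if (!ok) stop("implied covariance for group '", group_labels[g],
                  "' is not positive definite; check the true values",
                  call. = FALSE)
    Sigma
  })
  structure(list(model = model, values = values, ptab = ptab,
                 implied = implied, group_labels = group_labels,
                 var_order = var_order),
            class = "sem_true_model")
}

#' @export
print.sem_true_model <- function(x, ...) {
  cat("<sem_true_model>", length(x$implied), "group(s),",
      nrow(x$implied[[1]]), "observed variables\n")
  invisible(x)
}

#' True parameter values as a tibble
#' @param x A `sem_true_model`.
#' @param ... Unused.
#' @return Tibble with `lhs`, `op`, `rhs`, `group`, `free`, `true_value`.
#' @method tidy sem_true_model
#' @export
tidy.sem_true_model <- function(x, ...) {
  out <- x$ptab[c("lhs", "op", "rhs", "group", "free", "estimate")]
  names(out)[names(out) == "estimate"] <- "true_value"
  out$group <- x$group_labels[out$group]
  tibble::as_tibble(out)
}

#' Simulate a dataset from a true model
#'
#' Draws `n` multivariate-normal rows with the model-implied covariance and
#' zero means, deterministically per seed. For multi-group models `n` may be a
#' named vector (one entry per group) and the returned tibble carries the
#' grouping column.
#'
#' @param tm A `sem_true_model`.
#' @param n Number of rows (scalar, or named per-group vector).
#' @param seed Integer seed.
#' @return A tibble whose columns follow the model's observed-variable order.
#' @export
simulate_from <- function(tm, n, seed) {
  stopifnot(inherits(tm, "sem_true_model"), all(n >= 1))
  ng <- length(tm$implied)
  if (ng > 1L) {
    if (length(n) == 1L) n <- stats::setNames(rep(n, ng), tm$group_labels)
    n <- n[tm$group_labels]
    if (anyNA(n)) stop("n must be named by group label", call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- lapply(seq_len(ng), function(g) {
    Sigma <- tm$implied[[g]]
    p <- ncol(Sigma)
    Z <- matrix(stats::rnorm(n[g] * p), nrow = n[g], ncol = p)
    X <- Z %*% chol(Sigma)
    colnames(X) <- colnames(Sigma)
    d <- tibble::as_tibble(X)
    if (!is.null(tm$model$groups)) d[[tm$model$groups]] <- tm$group_labels[g]
    d
  })
  dplyr::bind_rows(out)
}

# derive a 32-bit-safe substream seed for replicate i of a run seeded with s
substream_seed <- function(s, i) {
  as.integer((as.double(s) %% 65011 + 1) * 32749 + i) %% 2147483629L
}
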