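#' Factor and composite scores
#'
#' Per-row scores for every unmeasured variable of a fitted model. Latent
#' scores use the regression method,
#' `score = (x - xbar) Sigma_xx^-1 Sigma_xL`, with model-implied covariances
#' and the training-group means; composite scores are the fitted weighted sum
#' of their (centered) causes, computed in topological order so composites of
#' latents work. These are the per-individual condition-index values that can
#' be extracted for plotting or downstream analysis.
#'
#' @param fit A converged `sem_fit`.
#' @param data Data frame with the model's observed variables; defaults to
#'   requiring the caller to pass the original data (moments carry no rows).
#' @return A tibble with `.row` (row index in `data`) and one column per
#'   latent and composite variable. Rows incomplete on the model variables are
#'   skipped with a warning naming their indices.
#' @export
sem_scores <- function(fit, data) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("cannot score a non-converged fit", call. = FALSE)
  data <- tibble::as_tibble(data)
  obs <- fit$var_order[fit$obs_idx]
  miss <- setdiff(c(obs, fit$model$groups), names(data))
  if (length(miss)) stop("data lacks model variables: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  unmeasured <- c(latent_vars(fit$model), composite_vars(fit$model))
  if (length(unmeasured) == 0L) {
    stop("model has no latent or composite variables to score", call. = FALSE)
  }
  complete <- stats::complete.cases(data[c(obs, fit$model$groups)])
  if (any(!complete)) {
    warning("skipping ", sum(!complete), " incomplete row(s): ",
            paste(utils::head(which(!complete), 10L), collapse = ", "),
            if (sum(!complete) > 10L) ", ..." else "", call. = FALSE)
  }
  if (!is.null(fit$model$groups)) {
    glab <- as.character(data[[fit$model$groups]])
    gidx <- match(glab, fit$group_labels)
    if (anyNA(gidx[complete])) {
      stop("data contains groups absent from the fit", call. = FALSE)
    }
  } else {
    gidx <- rep(1L, nrow(data))
  }
  out <- matrix(NA_real_, nrow(data), length(unmeasured),
                dimnames = list(NULL, unmeasured))
  comp <- composite_vars(fit$model)
  lat <- latent_vars(fit$model)
  # composites may cause other composites: topological order over composites
  comp_order <- topo_order_composites(fit$model)
  for (g in seq_len(fit$ngroups)) {
    rows <- which(complete & gidx == g)
    if (!length(rows)) next
    fic <- full_implied_cov(fit, g)
    V <- fic$V
    xbar <- fit$moments[[g]]$means[obs]
    Xc <- sweep(as.matrix(data[rows, obs, drop = FALSE]), 2, xbar)
    vals <- list()
    for (v in obs) vals[[v]] <- Xc[, v]
    if (length(lat)) {
      Sxx <- V[obs, obs, drop = FALSE]
      SxL <- V[obs, lat, drop = FALSE]
      Ls <- Xc %*% solve(Sxx, SxL)
      for (v in lat) vals[[v]] <- Ls[, v]
    }
    for (v in comp_order) {
      a_row <- fic$A[match(v, fit$var_order), ]
      parents <- fit$var_order[a_row != 0]
      sc <- rep(0, length(rows))
      for (p0 in parents) sc <- sc + a_row[match(p0, fit$var_order)] * vals[[p0]]
      vals[[v]] <- sc
    }
    for (v in unmeasured) out[rows, v] <- vals[[v]]
  }
  dplyr::bind_cols(tibble::tibble(.row = seq_len(nrow(data))),
                   tibble::as_tibble(out))
}

topo_order_composites <- function(m) {
  comp <- composite_vars(m)
  if (length(comp) <= 1L) return(comp)
  edges <- directed_edges(m)
  ordered <- character(0)
  remaining <- comp
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v) {
      parents <- edges$from[edges$to == v]
      !any(parents %in% remaining)
    }, logical(1))]
    if (!length(ready)) stop("cycle among composites", call. = FALSE)
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

#' Indirect effect along a path
#'
#' Product of standardized coefficients along an ordered chain of variables,
#' following the rules of path tracing: the mediated effect of, say, density
#' on survival through the condition index is the product of the
#' density -> condition and condition -> survival standardized paths.
#'
#' @param fit A `sem_fit` with the standardized solution filled.
#' @param path Character vector of variable names; consecutive pairs must be
#'   directed edges in the fitted model.
#' @param group Group index for multi-group fits (default 1).
#' @return The indirect effect (a single number).
#' @export
indirect_effect <- function(fit, path, group = 1L) {
  stopifnot(inherits(fit, "sem_fit"), length(path) >= 2L)
  pt <- fit$ptab[fit$ptab$group == group, ]
  eff <- 1
  for (k in seq_len(length(path) - 1L)) {
    from <- path[k]; to <- path[k + 1L]
    hit <- which((pt$op == "~" & pt$lhs == to & pt$rhs == from) |
                 (pt$op == "<~" & pt$lhs == to & pt$rhs == from) |
                 (pt$op == "=~" & pt$lhs == from & pt$rhs == to))
    if (!length(hit)) {
      stop("no directed edge ", from, " -> ", to, " in the fitted model",
           call. = FALSE)
    }
    eff <- eff * pt$std_estimate[hit[1]]
  }
  unname(eff)
}
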