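# Internal estimation machinery: parameter table, RAM matrices, ML discrepancy.
#
# The model is held in RAM (reticular action model) form over the full set of
# variables t = observed + latent + composite:
#   A    t x t  directed coefficients (loadings, regressions, composite weights)
#   S    t x t  symmetric variances/covariances (composite diagonal pinned to 0)
#   Fsel p x t  selector of the observed rows
# implied covariance:  Sigma = Fsel (I - A)^-1 S (I - A)^-T Fsel'

#' Sample moments for one group
#'
#' @param cov Symmetric p x p covariance matrix (denominator N - 1), with
#'   dimnames.
#' @param n Number of observations.
#' @param means Optional mean vector (defaults to zeros).
#' @return A `sem_moments` object.
#' @export
sem_moments <- function(cov, n, means = NULL) {
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == ncol(cov), !is.null(rownames(cov)))
  if (max(abs(cov - t(cov))) > 1e-10) stop("covariance matrix not symmetric",
                                           call. = FALSE)
  if (any(diag(cov) < 0)) stop("negative variance in covariance matrix", call. = FALSE)
  if (n < nrow(cov) + 1L) stop("need N >= p + 1 observations for fitting", call. = FALSE)
  if (is.null(means)) means <- stats::setNames(rep(0, nrow(cov)), rownames(cov))
  structure(list(cov = (cov + t(cov)) / 2, means = means, n = as.integer(n),
                 var_order = rownames(cov)),
            class = "sem_moments")
}

# order: observed (given), latents, composites
model_var_order <- function(m, obs_order) {
  c(obs_order, latent_vars(m), composite_vars(m))
}

# Build the per-group parameter table for an identified model.
build_param_table <- function(m, group_labels, moments) {
  stopifnot(m$identified)
  t1 <- canonical_terms(m$terms)
  t1$class <- term_class(t1)
  ng <- length(group_labels)
  ptab <- dplyr::bind_rows(lapply(seq_len(ng), function(g) {
    out <- t1
    out$group <- g
    out
  }))
  ptab$free <- is.na(ptab$fixed)
  # assign parameter indices; group_equal classes share one index across groups
  ptab$par <- 0L
  k <- 0L
  key1 <- paste(t1$lhs, t1$op, t1$rhs)
  shared_idx <- stats::setNames(rep(NA_integer_, nrow(t1)), key1)
  for (r in seq_len(nrow(ptab))) {
    if (!ptab$free[r]) next
    k0 <- paste(ptab$lhs[r], ptab$op[r], ptab$rhs[r])
    if (ptab$class[r] %in% m$group_equal) {
      if (is.na(shared_idx[[k0]])) { k <- k + 1L; shared_idx[[k0]] <- k }
      ptab$par[r] <- shared_idx[[k0]]
    } else {
      k <- k + 1L
      ptab$par[r] <- k
    }
  }
  ptab$start <- start_values(m, ptab, group_labels, moments)
  ptab$estimate <- ifelse(ptab$free, ptab$start, ptab$fixed)
  tibble::as_tibble(ptab)
}

# Start values: loadings 1, regressions 0, observed residual variances half
# the sample variance (full variance and covariance for the saturated
# exogenous block), latent variances half the variance of the scale indicator.
# Unknown-weight composites are special-cased: the product parameterization
# (weights x outcome slope) has a curved ridge through the default start, so
# weights and the outcome slope are seeded from the ordinary-least-squares
# solution of the outcome on (proxies of) the causes.
start_values <- function(m, ptab, group_labels, moments) {
  endo <- endogenous_vars(m)
  comp <- composite_vars(m)
  lat <- latent_vars(m)
  scale_ind <- vapply(lat, function(lv) {
    idx <- which(m$terms$op == "=~" & m$terms$lhs == lv)
    if (length(idx)) m$terms$rhs[idx[1]] else NA_character_
  }, character(1))
  # observed proxy for a composite cause: itself, or a latent's scale indicator
  proxy <- function(v) {
    if (v %in% lat) scale_ind[[v]] else if (v %in% comp) NA_character_ else v
  }
  comp_starts <- lapply(seq_along(group_labels), function(g) {
    S <- moments[[g]]$cov
    out <- c()
    for (cv in comp) {
      causes <- m$terms$rhs[m$terms$op == "<~" & m$terms$lhs == cv]
      outcome <- m$terms$lhs[m$terms$op == "~" & m$terms$rhs == cv]
      outcome <- outcome[outcome %in% rownames(S)]
      prox <- vapply(causes, proxy, character(1))
      if (!length(outcome) || anyNA(prox) || !all(prox %in% rownames(S))) next
      beta <- tryCatch(
        solve(S[prox, prox, drop = FALSE], S[prox, outcome[1], drop = FALSE])[, 1],
        error = function(e) NULL)
      if (is.null(beta) || abs(beta[1]) < 1e-8) next
      out[paste(cv, "<~", causes)] <- beta / beta[1]
      out[paste(outcome[1], "~", cv)] <- beta[1]
    }
    out
  })
  vapply(seq_len(nrow(ptab)), function(r) {
    if (!ptab$free[r]) return(ptab$fixed[r])
    op <- ptab$op[r]; lhs <- ptab$lhs[r]; rhs <- ptab$rhs[r]
    S <- moments[[ptab$group[r]]]$cov
    svar <- function(v) if (v %in% rownames(S)) S[v, v] else 1
    cs <- comp_starts[[ptab$group[r]]]
    key <- paste(lhs, op, rhs)
    if (key %in% names(cs)) return(cs[[key]])
    if (op %in% c("=~", "<~")) return(1)
    if (op == "~") return(0)
    # '~~' terms
    if (lhs == rhs) {
      if (lhs %in% comp) return(0)
      if (lhs %in% lat) {
        ind <- scale_ind[[lhs]]
        return(if (!is.na(ind)) svar(ind) / 2 else 0.5)
      }
      return(if (lhs %in% endo) svar(lhs) / 2 else svar(lhs))
    }
    both_exo_obs <- !(lhs %in% endo) && !(rhs %in% endo) &&
      lhs %in% rownames(S) && rhs %in% rownames(S)
    if (both_exo_obs) S[lhs, rhs] else 0
  }, numeric(1))
}

# Precompute fill/index structures for one group's RAM matrices.
ram_skeleton <- function(ptab_g, var_order) {
  t_n <- length(var_order)
  pos <- function(i, j) i + (j - 1L) * t_n
  idx <- match(ptab_g$lhs, var_order)
  jdx <- match(ptab_g$rhs, var_order)
  if (anyNA(idx) || anyNA(jdx)) {
    miss <- unique(c(ptab_g$lhs[is.na(idx)], ptab_g$rhs[is.na(jdx)]))
    stop("model variables not present in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  isA <- ptab_g$op %in% c("=~", "~", "<~")
  ai <- ifelse(ptab_g$op == "=~", jdx, idx)  # =~ : A[indicator, latent]
  aj <- ifelse(ptab_g$op == "=~", idx, jdx)
  list(
    t_n = t_n,
    a_pos = pos(ai[isA], aj[isA]),
    a_par = ptab_g$par[isA],
    a_val = ptab_g$fixed[isA],
    a_i = ai[isA], a_j = aj[isA],
    s_pos = pos(idx[!isA], jdx[!isA]),
    s_pos2 = pos(jdx[!isA], idx[!isA]),
    s_par = ptab_g$par[!isA],
    s_val = ptab_g$fixed[!isA],
    s_i = idx[!isA], s_j = jdx[!isA]
  )
}

ram_matrices <- function(skel, theta) {
  t_n <- skel$t_n
  A <- matrix(0, t_n, t_n)
  S <- matrix(0, t_n, t_n)
  av <- ifelse(skel$a_par > 0L, theta[pmax(skel$a_par, 1L)], skel$a_val)
  sv <- ifelse(skel$s_par > 0L, theta[pmax(skel$s_par, 1L)], skel$s_val)
  A[skel$a_pos] <- av
  S[skel$s_pos] <- sv
  S[skel$s_pos2] <- sv
  list(A = A, S = S)
}

#' Model-implied covariance matrix
#'
#' Computes `Fsel (I - A)^-1 S (I - A)^-T Fsel'`, the covariance matrix of the
#' observed variables implied by RAM coefficient matrix `A` and symmetric
#' (co)variance matrix `S`, with `obs` indexing the observed rows.
#'
#' @param A t x t directed-coefficient matrix.
#' @param S t x t symmetric variance/covariance matrix.
#' @param obs Integer (or logical) index of observed rows; default all.
#' @return Symmetric p x p implied covariance matrix.
#' @export
implied_covariance <- function(A, S, obs = seq_len(nrow(A))) {
  t_n <- nrow(A)
  B <- tryCatch(solve(diag(t_n) - A),
                error = function(e) stop("(I - A) is singular: the directed part ",
                                         "of the model contains a cycle", call. = FALSE))
  V <- B %*% S %*% t(B)
  Sigma <- V[obs, obs, drop = FALSE]
  (Sigma + t(Sigma)) / 2
}

#' Maximum-likelihood discrepancy
#'
#' The Wishart ML discrepancy between a sample covariance `S` and an implied
#' covariance `sigma`: `log det(Sigma) + tr(S Sigma^-1) - log det(S) - p`.
#' Non-negative, and zero exactly when the two matrices coincide.
#'
#' @param S Sample covariance matrix (positive definite).
#' @param sigma Implied covariance matrix (positive definite, same ordering).
#' @return The discrepancy value.
#' @export
discrepancy_fml <- function(S, sigma) {
  S <- as.matrix(S); sigma <- as.matrix(sigma)
  p <- nrow(S)
  stopifnot(nrow(sigma) == p)
  Rs <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite", call. = FALSE))
  Ri <- tryCatch(chol(sigma), error = function(e)
    stop("implied covariance is not positive definite", call. = FALSE))
  logdet_S <- 2 * sum(log(diag(Rs)))
  logdet_sigma <- 2 * sum(log(diag(Ri)))
  logdet_sigma + sum(diag(S %*% chol2inv(Ri))) - logdet_S - p
}

# Objective closure over all groups. Returns list(fn, gr, detail).
# weights w_g = (N_g - 1) (or N_g): total objective sum_g w_g * F_g = chisq.
make_objective <- function(skels, moments, obs_idx, weights) {
  ng <- length(skels)
  pre <- lapply(seq_len(ng), function(g) {
    S <- moments[[g]]$cov
    R <- tryCatch(chol(S), error = function(e)
      stop("sample covariance for group ", g, " is not positive definite",
           call. = FALSE))
    list(S = S, logdet = 2 * sum(log(diag(R))), p = nrow(S))
  })
  eval_group <- function(g, theta, grad = FALSE) {
    skel <- skels[[g]]
    ram <- ram_matrices(skel, theta)
    t_n <- skel$t_n
    ImA <- diag(t_n) - ram$A
    B <- tryCatch(solve(ImA), error = function(e) NULL)
    if (is.null(B)) return(NULL)
    V <- B %*% ram$S %*% t(B)
    Sigma <- V[obs_idx, obs_idx, drop = FALSE]
    Sigma <- (Sigma + t(Sigma)) / 2
    Rchol <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(Rchol)) return(NULL)
    Sinv <- chol2inv(Rchol)
    Sg <- pre[[g]]$S
    f <- 2 * sum(log(diag(Rchol))) + sum(Sinv * Sg) - pre[[g]]$logdet - pre[[g]]$p
    if (!grad) return(list(f = f))
    E <- Sinv - Sinv %*% Sg %*% Sinv
    EF <- matrix(0, t_n, t_n)
    EF[obs_idx, obs_idx] <- E
    EFB <- EF %*% B
    M <- t(B) %*% EFB                       # gradient wrt S entries
    G <- (B %*% ram$S %*% t(B)) %*% EFB     # gradient wrt A entries (use G[j,i])
    gvec <- numeric(max_par(skels))
    fa <- skel$a_par > 0L
    if (any(fa)) {
      contrib <- 2 * G[cbind(skel$a_j[fa], skel$a_i[fa])]
      gvec[skel$a_par[fa]] <- gvec[skel$a_par[fa]] + contrib
    }
    fs <- skel$s_par > 0L
    if (any(fs)) {
      di <- skel$s_i[fs] == skel$s_j[fs]
      contrib <- ifelse(di, M[cbind(skel$s_i[fs], skel$s_j[fs])],
                        2 * M[cbind(skel$s_i[fs], skel$s_j[fs])])
      gvec[skel$s_par[fs]] <- gvec[skel$s_par[fs]] + contrib
    }
    list(f = f, g = gvec)
  }
  max_par <- function(skels) max(0L, unlist(lapply(skels, function(s)
    c(s$a_par, s$s_par))))
  npar <- max_par(skels)
  fn <- function(theta) {
    tot <- 0
    for (g in seq_len(ng)) {
      r <- eval_group(g, theta, grad = FALSE)
      if (is.null(r)) return(1e12)
      tot <- tot + weights[g] * r$f
    }
    tot
  }
  gr <- function(theta) {
    gtot <- numeric(npar)
    for (g in seq_len(ng)) {
      r <- eval_group(g, theta, grad = TRUE)
      if (is.null(r)) return(gtot)  # flat gradient inside the penalty region
      gtot <- gtot + weights[g] * r$g
    }
    gtot
  }
  fml <- function(theta) {
    vapply(seq_len(ng), function(g) {
      r <- eval_group(g, theta, grad = FALSE)
      if (is.null(r)) NA_real_ else r$f
    }, numeric(1))
  }
  list(fn = fn, gr = gr, fml = fml, npar = npar)
}
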