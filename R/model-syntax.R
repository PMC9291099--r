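#' Parse SEM model syntax
#'
#' Parses a line-oriented model description into a `sem_model` object. The
#' syntax follows the de-facto SEM convention used throughout the applied
#' literature:
#'
#' * `latent =~ ind1 + ind2` — measurement: the latent variable on the left is
#'   measured by the indicators on the right (loadings).
#' * `y ~ x1 + x2` — regression of the left-hand variable on the right-hand
#'   predictors.
#' * `comp <~ x1 + x2` — composite definition: the left-hand variable is the
#'   weighted sum of its causes, with residual variance fixed to zero.
#' * `a ~~ b` — (residual) covariance; `a ~~ a` a variance.
#'
#' A right-hand term may carry a fixed value (`1*mass`) or a label
#' (`lam1*mass`). Lines starting with `#` (or trailing `#` comments) are
#' ignored. Undeclared names become latent when they appear on the left of
#' `=~`, composite on the left of `<~`, and observed otherwise.
#'
#' @param text Model syntax as a single string (newline separated) or a
#'   character vector of lines.
#' @param groups Optional name of a grouping column for multi-group analysis.
#' @param group_equal Character vector of parameter classes constrained equal
#'   across groups: any of `"loadings"`, `"regressions"`, `"residuals"`.
#'   Default none (fully separate per-group parameters).
#' @param meanstructure Include intercepts/means? Default `FALSE`
#'   (covariance-only analysis).
#' @return A `sem_model` object: a list with tibbles `variables`
#'   (name, role) and `terms` (lhs, op, rhs, fixed, label), plus the group
#'   settings and an `identified` flag.
#' @examples
#' m <- sem_model("energy =~ mass + ratio\nenergy ~ tarsus + head + wing")
#' m
#' @export
sem_model <- function(text, groups = NULL, group_equal = character(),
                      meanstructure = FALSE) {
  stopifnot(is.character(text), length(text) >= 1L)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    stop("empty model syntax", call. = FALSE)
  }
  ops <- c("=~", "<~", "~~", "~")  # match order matters: '~' last
  terms <- list()
  roles <- character(0) # named character: name -> role
  note_role <- function(name, role, force = FALSE) {
    known <- name %in% names(roles)
    if (!known || (force && roles[[name]] == "observed")) roles[[name]] <- role
    roles
  }
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    # locate the operator by fixed search in priority order ('~' last)
    op <- NULL
    for (o in ops) {
      if (grepl(o, line, fixed = TRUE)) { op <- o; break }
    }
    if (is.null(op)) {
      stop(sprintf("syntax error on line %d: no operator found in \"%s\"", i, line),
           call. = FALSE)
    }
    pieces <- strsplit(line, op, fixed = TRUE)[[1]]
    if (length(pieces) != 2L || !nzchar(trimws(pieces[1])) || !nzchar(trimws(pieces[2]))) {
      stop(sprintf("syntax error on line %d: expected \"lhs %s rhs\"", i, op),
           call. = FALSE)
    }
    lhs <- trimws(pieces[1])
    if (!grepl("^[A-Za-z.][A-Za-z0-9._']*$", lhs)) {
      stop(sprintf("syntax error on line %d: invalid left-hand name \"%s\"", i, lhs),
           call. = FALSE)
    }
    roles <- note_role(lhs, switch(op, "=~" = "latent", "<~" = "composite", "observed"),
                       force = op %in% c("=~", "<~"))
    rhs_terms <- trimws(strsplit(pieces[2], "+", fixed = TRUE)[[1]])
    if (any(!nzchar(rhs_terms))) {
      stop(sprintf("syntax error on line %d: empty right-hand term", i), call. = FALSE)
    }
    for (rt in rhs_terms) {
      fixed <- NA_real_
      label <- NA_character_
      name <- rt
      if (grepl("*", rt, fixed = TRUE)) {
        bits <- trimws(strsplit(rt, "*", fixed = TRUE)[[1]])
        if (length(bits) != 2L || !nzchar(bits[1]) || !nzchar(bits[2])) {
          stop(sprintf("syntax error on line %d: malformed modifier \"%s\"", i, rt),
               call. = FALSE)
        }
        val <- suppressWarnings(as.numeric(bits[1]))
        if (!is.na(val)) fixed <- val else label <- bits[1]
        name <- bits[2]
      }
      if (!grepl("^[A-Za-z.][A-Za-z0-9._']*$", name)) {
        stop(sprintf("syntax error on line %d: invalid name \"%s\"", i, name),
             call. = FALSE)
      }
      roles <- note_role(name, "observed")
      terms[[length(terms) + 1L]] <- tibble::tibble(
        lhs = lhs, op = op, rhs = name, fixed = fixed, label = label)
    }
  }
  terms <- dplyr::bind_rows(terms)
  terms <- merge_duplicate_terms(terms)
  # composite definition implies a residual variance pinned to zero
  for (comp in names(roles)[roles == "composite"]) {
    if (!any(terms$op == "~~" & terms$lhs == comp & terms$rhs == comp)) {
      terms <- dplyr::bind_rows(terms, tibble::tibble(
        lhs = comp, op = "~~", rhs = comp, fixed = 0, label = NA_character_))
    }
  }
  bad <- setdiff(group_equal, c("loadings", "regressions", "residuals"))
  if (length(bad)) stop("unknown group_equal class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- structure(list(
    variables = tibble::tibble(name = names(roles), role = unname(roles)),
    terms = terms,
    groups = groups,
    group_equal = group_equal,
    meanstructure = meanstructure,
    identified = FALSE
  ), class = "sem_model")
  validate_sem_model(out)
  out
}

# collapse duplicate (lhs, op, rhs) rows; '~~' keyed order-insensitively
canonical_terms <- function(terms) {
  sym <- terms$op == "~~"
  a <- terms$lhs; b <- terms$rhs
  lo <- pmin(a, b); hi <- pmax(a, b)
  terms$lhs[sym] <- lo[sym]
  terms$rhs[sym] <- hi[sym]
  terms
}

merge_duplicate_terms <- function(terms) {
  if (nrow(terms) == 0L) return(terms)
  terms <- canonical_terms(terms)
  key <- paste(terms$lhs, terms$op, terms$rhs)
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      fx <- terms$fixed[key == k]
      fx <- fx[!is.na(fx)]
      if (length(unique(fx)) > 1L) {
        stop("conflicting fixed values for term: ", k, call. = FALSE)
      }
    }
    terms <- terms |>
      dplyr::mutate(.key = key) |>
      dplyr::group_by(.key) |>
      dplyr::summarise(
        lhs = lhs[1], op = op[1], rhs = rhs[1],
        fixed = if (all(is.na(fixed))) NA_real_ else fixed[!is.na(fixed)][1],
        label = if (all(is.na(label))) NA_character_ else label[!is.na(label)][1],
        .groups = "drop") |>
      dplyr::select(-".key")
  }
  terms
}

validate_sem_model <- function(m) {
  stopifnot(inherits(m, "sem_model"))
  if (anyDuplicated(m$variables$name)) {
    stop("duplicate variable names in model", call. = FALSE)
  }
  # directed part must be acyclic
  dir_ops <- m$terms$op %in% c("=~", "~", "<~")
  if (any(dir_ops)) {
    edges <- directed_edges(m)
    if (has_cycle(edges, m$variables$name)) {
      stop("directed part of the model contains a cycle", call. = FALSE)
    }
  }
  invisible(m)
}

# directed edges as from -> to in the causal direction
directed_edges <- function(m) {
  t <- m$terms
  from <- character(0); to <- character(0)
  mb <- t$op == "=~"           # latent -> indicator
  from <- c(from, t$lhs[mb]); to <- c(to, t$rhs[mb])
  rg <- t$op == "~"            # rhs -> lhs
  from <- c(from, t$rhs[rg]); to <- c(to, t$lhs[rg])
  cp <- t$op == "<~"           # cause -> composite
  from <- c(from, t$rhs[cp]); to <- c(to, t$lhs[cp])
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

has_cycle <- function(edges, nodes) {
  adj <- split(edges$to, factor(edges$from, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 visiting, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]]) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  for (v in nodes) if (visit(v)) return(TRUE)
  FALSE
}

variable_role <- function(m, name) {
  m$variables$role[match(name, m$variables$name)]
}

observed_vars <- function(m) m$variables$name[m$variables$role == "observed"]
latent_vars <- function(m) m$variables$name[m$variables$role == "latent"]
composite_vars <- function(m) m$variables$name[m$variables$role == "composite"]

# variables with an incoming directed edge
endogenous_vars <- function(m) {
  unique(directed_edges(m)$to)
}

#' Serialize a model to canonical syntax
#'
#' Writes a `sem_model` back to the line-oriented syntax accepted by
#' [sem_model()]. `parse(serialize(m))` is the identity on canonicalized
#' models, which the test-suite exercises as a round-trip property.
#'
#' @param m A `sem_model`.
#' @return A single string of model syntax.
#' @export
serialize_model <- function(m) {
  stopifnot(inherits(m, "sem_model"))
  t <- canonical_terms(m$terms)
  t <- t[order(match(t$op, c("=~", "<~", "~", "~~")), t$lhs, t$rhs), ]
  fmt_rhs <- function(fixed, label, rhs) {
    pre <- ifelse(!is.na(fixed), paste0(format(fixed, digits = 15), "*"),
                  ifelse(!is.na(label), paste0(label, "*"), ""))
    paste0(pre, rhs)
  }
  lines <- t |>
    dplyr::mutate(rhs_txt = fmt_rhs(fixed, label, rhs)) |>
    dplyr::group_by(lhs, op) |>
    dplyr::summarise(line = paste(lhs[1], op[1], paste(rhs_txt, collapse = " + ")),
                     .groups = "drop")
  paste(lines$line, collapse = "\n")
}

#' @export
print.sem_model <- function(x, ...) {
  cat("<sem_model>", if (x$identified) "(identified)" else "(raw)", "\n")
  n <- table(factor(x$variables$role, levels = c("observed", "latent", "composite")))
  cat(sprintf("  %d observed, %d latent, %d composite; %d terms\n",
              n[["observed"]], n[["latent"]], n[["composite"]], nrow(x$terms)))
  if (!is.null(x$groups)) cat("  groups:", x$groups, "\n")
  cat(serialize_model(x), "\n")
  invisible(x)
}

#' Apply identification rules to a model
#'
#' Completes a raw model into a fittable, identified one:
#'
#' * every latent without a user-set scale constraint gets its first listed
#'   loading fixed to 1 (or its variance fixed to 1 when `std_lv = TRUE`);
#' * every composite without a scale constraint gets its first listed cause
#'   weight fixed to 1, and its residual variance pinned to 0;
#' * every endogenous variable gets a free residual variance (composites
#'   excepted);
#' * exogenous observed variables get free variances and pairwise covariances,
#'   and exogenous latents likewise, unless the user already supplied the term
#'   (fixing a covariance to 0 suppresses it).
#'
#' The operation is idempotent.
#'
#' @param m A `sem_model`.
#' @param std_lv Scale latents by fixing their (residual) variance to 1
#'   instead of the first loading. Default `FALSE`.
#' @return The identified `sem_model`.
#' @export
apply_identification <- function(m, std_lv = FALSE) {
  stopifnot(inherits(m, "sem_model"))
  t <- canonical_terms(m$terms)
  has_term <- function(lhs, op, rhs) {
    if (op == "~~") { lo <- pmin(lhs, rhs); hi <- pmax(lhs, rhs); lhs <- lo; rhs <- hi }
    any(t$lhs == lhs & t$op == op & t$rhs == rhs)
  }
  add_term <- function(lhs, rhs, fixed) {
    lo <- min(lhs, rhs); hi <- max(lhs, rhs)
    t <<- dplyr::bind_rows(t, tibble::tibble(lhs = lo, op = "~~", rhs = hi,
                                             fixed = fixed,
                                             label = NA_character_))
  }
  for (lv in latent_vars(m)) {
    loads <- which(t$op == "=~" & t$lhs == lv)
    regs <- which(t$op == "~" & t$lhs == lv)
    if (length(loads) == 0L && length(regs) == 0L) {
      stop("latent variable '", lv, "' has no indicators and no covariate regressions",
           call. = FALSE)
    }
    scale_set <- any(!is.na(t$fixed[loads])) ||
      any(t$op == "~~" & t$lhs == lv & t$rhs == lv & !is.na(t$fixed))
    if (!scale_set) {
      if (std_lv || length(loads) == 0L) {
        # unit latent variance (also the MIMIC-style latent defined only
        # through regressions, which has no loading to fix)
        if (!has_term(lv, "~~", lv)) {
          add_term(lv, lv, 1)
        } else {
          t$fixed[t$op == "~~" & t$lhs == lv & t$rhs == lv] <- 1
        }
      } else {
        t$fixed[loads[1]] <- 1
      }
    }
  }
  for (cv in composite_vars(m)) {
    w <- which(t$op == "<~" & t$lhs == cv)
    if (length(w) == 0L) stop("composite '", cv, "' has no causes", call. = FALSE)
    out_paths <- which(t$op == "~" & t$rhs == cv)
    scale_set <- any(!is.na(t$fixed[w])) || any(!is.na(t$fixed[out_paths]))
    if (!scale_set) t$fixed[w[1]] <- 1
    dvar <- which(t$op == "~~" & t$lhs == cv & t$rhs == cv)
    if (length(dvar)) t$fixed[dvar] <- 0 else add_term(cv, cv, 0)
  }
  endo <- endogenous_vars(m)
  # residual variances for endogenous variables (not composites)
  for (v in setdiff(endo, composite_vars(m))) {
    if (!has_term(v, "~~", v)) add_term(v, v, NA_real_)
  }
  exo_obs <- setdiff(observed_vars(m), endo)
  exo_lat <- setdiff(latent_vars(m), endo)
  add_block <- function(vars) {
    if (length(vars) == 0L) return()
    for (i in seq_along(vars)) {
      if (!has_term(vars[i], "~~", vars[i])) add_term(vars[i], vars[i], NA_real_)
      if (i < length(vars)) {
        for (j in (i + 1L):length(vars)) {
          if (!has_term(vars[i], "~~", vars[j])) {
            add_term(vars[i], vars[j], NA_real_)
          }
        }
      }
    }
  }
  add_block(exo_obs)
  # exogenous latents keep their std_lv-fixed variance; covariances are free
  add_block(exo_lat)
  m$terms <- t
  m$identified <- TRUE
  validate_sem_model(m)
  m
}

#' Model degrees of freedom
#'
#' Degrees of freedom of the covariance-structure analysis:
#' `n_groups * p * (p + 1) / 2` sample moments (plus `n_groups * p` means when
#' the mean structure is enabled) minus the number of free parameters, with
#' cross-group equality constraints counted once.
#'
#' @param m An identified `sem_model` (see [apply_identification()]).
#' @param p Number of observed variables; defaults to the count in the model.
#' @param n_groups Number of groups; default 1.
#' @return Integer degrees of freedom. Negative values signal an
#'   under-identified model and raise an error.
#' @export
model_df <- function(m, p = length(observed_vars(m)), n_groups = 1L) {
  stopifnot(inherits(m, "sem_model"))
  if (!m$identified) m <- apply_identification(m)
  nfree1 <- sum(is.na(m$terms$fixed))
  classes <- term_class(m$terms)
  shared <- classes %in% m$group_equal & is.na(m$terms$fixed)
  nfree <- nfree1 * n_groups - sum(shared) * (n_groups - 1L)
  moments <- n_groups * p * (p + 1) / 2
  if (m$meanstructure) {
    moments <- moments + n_groups * p
    nfree <- nfree + n_groups * p  # free intercepts/means by default
  }
  df <- as.integer(moments - nfree)
  if (df < 0L) {
    stop("model is under-identified: ", nfree, " free parameters for ",
         moments, " sample moments (df = ", df, ")", call. = FALSE)
  }
  df
}

term_class <- function(terms) {
  dplyr::case_when(
    terms$op == "=~" ~ "loadings",
    terms$op %in% c("~", "<~") ~ "regressions",
    TRUE ~ "residuals")
}
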