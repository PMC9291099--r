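#' Named condition-model structures
#'
#' Programmatic builders for the model structures used in fitness-anchored
#' body-condition analysis. Role names (left) are rewritten to dataset column
#' names through `map`:
#'
#' * `energy_cfa` — latent energy stores measured by body mass and the
#'   mass/tarsus ratio, with the three structural sizes regressing on the
#'   latent (the MIMIC block that also makes the 2-indicator factor
#'   identified; the builder refuses to emit the factor without it).
#' * `bill_colour_cfa_multigroup` — bill-colour latent measured by hue,
#'   chroma and luminance, grouped by age class with fully separate per-group
#'   parameters.
#' * `size_corrected_mass_mimic` — latent size-corrected mass carrying the
#'   single indicator mass (loading 1) with tarsus/head/wing regressing on the
#'   latent. Standalone, the indicator residual is pinned to 0 (otherwise the
#'   variance split is not identified); inside the joint condition models it
#'   is left free because the composite-to-survival channel identifies it.
#' * `condition_composite` — unknown-weight composite of six condition
#'   variables (size-corrected mass plus five physiological measures)
#'   predicting survival, with competitor density regressed on the composite
#'   in the same model (density does not enter the composite definition).
#' * `full_model` — replaces size-corrected mass with the energy-stores
#'   latent (sizes and handling time regress on it), adds hue, MIMIC
#'   confounder corrections via primed latents, and the
#'   haematocrit ~~ cholesterol error covariance.
#' * `full_model_with_bodysize` — the competing hypothesis: a structural-size
#'   latent measured by tarsus/head/wing takes over the size regressions and
#'   gains a direct path to survival.
#' * `quadratic_mass` — `condition_composite` plus a squared-mass cause with
#'   the mass ~~ squared-mass error covariance (the data must contain the
#'   squared, preferably centered-then-squared, mass column).
#'
#' @param variant One of the names above.
#' @param map Named character vector mapping role names (`mass`, `tarsus`,
#'   `head`, `wing`, `ratio`, `hue`, `chroma`, `luminance`, `buffy_coat`,
#'   `haematocrit`, `cholesterol`, `uric_acid`, `corticosterone`, `survival`,
#'   `density`, `sex`, `age_class`, `handling_time`, `bill_tip`, `mass_sq`)
#'   to dataset column names. Unmapped roles keep their own name.
#' @param include_density Keep the density regression on the composite?
#'   Default `TRUE`; set `FALSE` for the cross-validation form of the model.
#' @param include_sizes `energy_cfa` only; must remain `TRUE` (a standalone
#'   2-indicator factor is under-identified).
#' @param confounder_edges `full_model` variants: named list giving, per
#'   corrected variable role (`hue`, `buffy_coat`, `haematocrit`,
#'   `cholesterol`, `uric_acid`, `corticosterone`), the confounder roles that
#'   regress on its primed latent. Defaults: hue gets `bill_tip` and `sex`;
#'   each physiological variable gets `sex`, `age_class` and `handling_time`.
#' @return An identified `sem_model`.
#' @examples
#' condition_model("condition_composite")
#' @export
condition_model <- function(variant = c("energy_cfa", "bill_colour_cfa_multigroup",
                                        "size_corrected_mass_mimic",
                                        "condition_composite", "full_model",
                                        "full_model_with_bodysize",
                                        "quadratic_mass"),
                            map = NULL, include_density = TRUE,
                            include_sizes = TRUE, confounder_edges = NULL) {
  variant <- match.arg(variant)
  roles <- c("mass", "tarsus", "head", "wing", "ratio", "hue", "chroma",
             "luminance", "buffy_coat", "haematocrit", "cholesterol",
             "uric_acid", "corticosterone", "survival", "density",
             "sex", "age_class", "handling_time", "bill_tip", "mass_sq")
  if (!is.null(map)) {
    bad <- setdiff(names(map), roles)
    if (length(bad)) stop("unknown role(s) in map: ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  v <- function(role) {
    if (!is.null(map) && role %in% names(map)) unname(map[[role]]) else role
  }
  phys <- c("buffy_coat", "haematocrit", "cholesterol", "uric_acid",
            "corticosterone")
  groups <- NULL
  lines <- switch(variant,
    energy_cfa = {
      if (!include_sizes) {
        stop("a standalone 2-indicator energy factor is under-identified; ",
             "the size-regression block is required", call. = FALSE)
      }
      c(sprintf("energy =~ %s + %s", v("mass"), v("ratio")),
        sprintf("energy ~ %s + %s + %s", v("tarsus"), v("head"), v("wing")))
    },
    bill_colour_cfa_multigroup = {
      groups <- v("age_class")
      sprintf("colour =~ %s + %s + %s", v("hue"), v("chroma"), v("luminance"))
    },
    size_corrected_mass_mimic = {
      c(sprintf("size_corrected_mass =~ 1*%s", v("mass")),
        sprintf("%s ~~ 0*%s", v("mass"), v("mass")),
        sprintf("size_corrected_mass ~ %s + %s + %s",
                v("tarsus"), v("head"), v("wing")))
    },
    condition_composite = ,
    quadratic_mass = {
      causes <- c("size_corrected_mass", vapply(phys, v, character(1)))
      if (variant == "quadratic_mass") causes <- c(causes, v("mass_sq"))
      out <- c(
        sprintf("size_corrected_mass =~ 1*%s", v("mass")),
        sprintf("size_corrected_mass ~ %s + %s + %s",
                v("tarsus"), v("head"), v("wing")),
        paste("condition <~", paste(causes, collapse = " + ")),
        if (include_density) sprintf("condition ~ %s", v("density")),
        sprintf("%s ~ condition", v("survival")))
      if (variant == "quadratic_mass") {
        out <- c(out, sprintf("%s ~~ %s", v("mass"), v("mass_sq")))
      }
      out
    },
    full_model = ,
    full_model_with_bodysize = {
      edges <- confounder_edges %||% c(
        list(hue = c("bill_tip", "sex")),
        stats::setNames(rep(list(c("sex", "age_class", "handling_time")),
                            length(phys)), phys))
      primed <- function(role) paste0(sub("_.*$", "", role), "_c")
      corrected <- c("hue", phys)
      prime_names <- vapply(corrected, primed, character(1))
      # single-indicator primed latents: the indicator residual is pinned to 0
      # so the latent's residual variance carries the corrected variance (the
      # free-split alternative is barely identified in this structure)
      mimic <- unlist(lapply(corrected, function(role) {
        conf <- vapply(edges[[role]], v, character(1))
        c(sprintf("%s =~ 1*%s", primed(role), v(role)),
          sprintf("%s ~~ 0*%s", v(role), v(role)),
          if (length(conf)) sprintf("%s ~ %s", primed(role),
                                    paste(conf, collapse = " + ")))
      }))
      size_block <- if (variant == "full_model") {
        sprintf("energy ~ %s + %s + %s + %s", v("tarsus"), v("head"), v("wing"),
                v("handling_time"))
      } else {
        c(sprintf("bodysize =~ %s + %s + %s", v("tarsus"), v("head"), v("wing")),
          sprintf("energy ~ bodysize + %s", v("handling_time")),
          sprintf("%s ~ bodysize", v("survival")))
      }
      c(sprintf("energy =~ %s + %s", v("mass"), v("ratio")),
        size_block,
        mimic,
        paste("condition <~", paste(c("energy", prime_names), collapse = " + ")),
        if (include_density) sprintf("condition ~ %s", v("density")),
        sprintf("%s ~ condition", v("survival")),
        # correlated errors of haematocrit and cholesterol, carried by the
        # primed latents because the indicator residuals are pinned
        sprintf("%s ~~ %s", primed("haematocrit"), primed("cholesterol")))
    })
  if (variant == "bill_colour_cfa_multigroup") groups <- v("age_class")
  m <- sem_model(paste(lines, collapse = "\n"), groups = groups)
  apply_identification(m)
}
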