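# Packaged oystercatcher-like true models. All numeric values below are
# fixture choices (one source of truth, used by tests and the acceptance
# script alike), sized to emulate the qualitative structure of the case-study
# population: two strongly correlated energy-store measures (r ~ 0.9), colour
# components whose intercorrelation differs by age class, weakly
# intercorrelated physiological variables, confounders, and a continuous
# area-level survival response with a density covariate. They are NOT
# estimates from any real dataset.

#' Packaged true models for synthetic data
#'
#' Returns a documented [sem_true_model()] emulating the correlation structure
#' of a shorebird condition study:
#'
#' * `"energy"` — energy-stores latent with two indicators (mass and the
#'   mass/size ratio, implied correlation about 0.9) and three structural
#'   sizes regressing on the latent.
#' * `"colour_grouped"` — hue/chroma/luminance colour factor with high adult
#'   and low sub-adult intercorrelation, grouped by `age_class`.
#' * `"condition"` — the joint condition model: size-corrected-mass latent
#'   (measurement error on mass), an unknown-weight composite of six condition
#'   variables with two dominant weights (size-corrected mass fixed at 1,
#'   corticosterone -0.8) and four near zero, density -> condition negative,
#'   condition -> survival positive. Structural sizes covary with
#'   corticosterone, which is what makes the stepwise residual-regression
#'   estimator biased while the joint SEM is not.
#' * `"full"` — the full structure: energy latent, hue and the five
#'   physiological variables corrected for confounders through primed MIMIC
#'   latents, the haematocrit/cholesterol error covariance, composite
#'   condition, density and survival.
#'
#' @param kind One of `"energy"`, `"colour_grouped"`, `"condition"`, `"full"`.
#' @return A `sem_true_model`.
#' @export
condition_fixture <- function(kind = c("energy", "colour_grouped", "condition",
                                       "full")) {
  kind <- match.arg(kind)
  switch(kind,
    energy = fixture_energy(),
    colour_grouped = fixture_colour_grouped(),
    condition = fixture_condition(),
    full = fixture_full())
}

fixture_energy <- function() {
  m <- condition_model("energy_cfa")
  sizes <- c("tarsus", "head", "wing")
  vals <- c(
    "energy =~ ratio" = 0.95,
    "energy ~ tarsus" = 0.30, "energy ~ head" = 0.20, "energy ~ wing" = 0.20,
    "energy ~~ energy" = 0.80,
    "mass ~~ mass" = 0.10, "ratio ~~ ratio" = 0.12,
    block_values(sizes, var = 1, cov = 0.5))
  sem_true_model(m, vals)
}

fixture_colour_grouped <- function() {
  m <- condition_model("bill_colour_cfa_multigroup")
  adult <- c(
    "colour =~ chroma" = -0.90, "colour =~ luminance" = 0.95,
    "colour ~~ colour" = 0.80,
    "hue ~~ hue" = 0.20, "chroma ~~ chroma" = 0.35,
    "luminance ~~ luminance" = 0.25)
  subadult <- c(
    "colour =~ chroma" = 1.80, "colour =~ luminance" = 1.60,
    "colour ~~ colour" = 0.15,
    "hue ~~ hue" = 0.85, "chroma ~~ chroma" = 0.40,
    "luminance ~~ luminance" = 0.45)
  sem_true_model(m, list(adult = adult, subadult = subadult))
}

# weights of the condition composite and the structural paths; exported so the
# evaluation harness and tests share a single source of truth
condition_fixture_truth <- function() {
  list(
    weights = c(size_corrected_mass = 1, buffy_coat = 0.10, haematocrit = 0.10,
                cholesterol = 0.05, uric_acid = 0.05, corticosterone = -0.80),
    survival_on_condition = 0.45,
    condition_on_density = -0.35)
}

fixture_condition <- function() {
  m <- condition_model("condition_composite")
  truth <- condition_fixture_truth()
  phys <- c("buffy_coat", "haematocrit", "cholesterol", "uric_acid",
            "corticosterone")
  sizes <- c("tarsus", "head", "wing")
  exo <- c(sizes, phys, "density")
  w <- truth$weights
  vals <- c(
    "size_corrected_mass ~ tarsus" = 0.25,
    "size_corrected_mass ~ head" = 0.20,
    "size_corrected_mass ~ wing" = 0.15,
    "size_corrected_mass ~~ size_corrected_mass" = 0.60,
    "mass ~~ mass" = 0.20,
    stats::setNames(unname(w[phys]), paste("condition <~", phys)),
    "condition ~ density" = truth$condition_on_density,
    "survival ~ condition" = truth$survival_on_condition,
    "survival ~~ survival" = 0.60,
    block_values(exo, var = 1, cov = 0),
    block_values(sizes, var = NA, cov = 0.5),
    block_values(phys, var = NA, cov = 0.1),
    "tarsus ~~ corticosterone" = -0.30,
    "head ~~ corticosterone" = -0.20)
  vals <- collapse_values(vals)
  sem_true_model(m, vals)
}

fixture_full <- function() {
  m <- condition_model("full_model")
  phys <- c("buffy_coat", "haematocrit", "cholesterol", "uric_acid",
            "corticosterone")
  primed <- c("buffy_c", "haematocrit_c", "cholesterol_c", "uric_c",
              "corticosterone_c")
  sizes <- c("tarsus", "head", "wing")
  exo <- c(sizes, "handling_time", "bill_tip", "sex", "age_class", "density")
  vals <- c(
    "energy =~ ratio" = 0.95,
    "energy ~ tarsus" = 0.25, "energy ~ head" = 0.20, "energy ~ wing" = 0.15,
    "energy ~ handling_time" = -0.20,
    "energy ~~ energy" = 0.60,
    "mass ~~ mass" = 0.15, "ratio ~~ ratio" = 0.15,
    "hue_c ~ bill_tip" = 0.25, "hue_c ~ sex" = -0.30,
    "hue_c ~~ hue_c" = 0.80,
    stats::setNames(rep(0.20, 5), paste0(primed, " ~ sex")),
    stats::setNames(rep(0.20, 5), paste0(primed, " ~ age_class")),
    stats::setNames(rep(-0.20, 5), paste0(primed, " ~ handling_time")),
    stats::setNames(rep(0.80, 5), paste0(primed, " ~~ ", primed)),
    "haematocrit_c ~~ cholesterol_c" = 0.10,
    "condition <~ hue_c" = 0.10, "condition <~ buffy_c" = 0.10,
    "condition <~ haematocrit_c" = 0.05, "condition <~ cholesterol_c" = 0.05,
    "condition <~ uric_c" = 0.05, "condition <~ corticosterone_c" = -0.70,
    "condition ~ density" = -0.35,
    "survival ~ condition" = 0.45,
    "survival ~~ survival" = 0.60,
    block_values(exo, var = 1, cov = 0),
    block_values(sizes, var = NA, cov = 0.5))
  vals <- collapse_values(vals)
  sem_true_model(m, vals)
}

# named values for a saturated exogenous block: variances and all pairwise
# covariances; var = NA emits covariances only (for overriding a sub-block)
block_values <- function(vars, var = 1, cov = 0) {
  out <- c()
  if (!is.na(var)) {
    out <- stats::setNames(rep(var, length(vars)), paste0(vars, " ~~ ", vars))
  }
  if (length(vars) > 1L) {
    pairs <- utils::combn(sort(vars), 2)
    out <- c(out, stats::setNames(rep(cov, ncol(pairs)),
                                  paste(pairs[1, ], "~~", pairs[2, ])))
  }
  out
}

# later entries win (lets a sub-block override the default block)
collapse_values <- function(vals) {
  nm <- names(vals)
  canon <- vapply(strsplit(nm, "\\s+"), function(b) {
    if (length(b) == 3L && b[2] == "~~") {
      paste(min(b[1], b[3]), "~~", max(b[1], b[3]))
    } else paste(b, collapse = " ")
  }, character(1))
  keep <- !duplicated(canon, fromLast = TRUE)
  stats::setNames(unname(vals[keep]), canon[keep])
}
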