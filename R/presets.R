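#' Published reference values for the four diamondback moth strains
#'
#' Mean life-history and population parameters reported for the wild-type
#' (WT) strain and the three trehalose-transporter knockout strains of
#' *Plutella xylostella* (MU-1: 1 bp deletion, MU-2: 2 bp deletion,
#' MU+14: 14 bp insertion), as published: per-stage developmental times,
#' adult longevity by sex, adult and total pre-oviposition periods,
#' oviposition days and per-female fecundity, and the population parameters
#' r (intrinsic rate of increase, per day), R0 (net reproductive rate,
#' offspring/individual), T (mean generation time, days) and lambda
#' (finite rate of increase, per day). These are the calibration targets of
#' [preset_from_table()] and the inputs to the internal-consistency checks
#' of the acceptance suite.
#'
#' @return data.frame with one row per strain and one column per parameter.
#' @export
#' @examples
#' strain_reference_values()[, c("strain", "R0", "T", "r")]
strain_reference_values <- function() {
  data.frame(
    strain = c("WT", "MU-1", "MU-2", "MU+14"),
    egg = c(3.00, 3.10, 3.00, 3.00),
    larva = c(5.11, 6.58, 6.14, 6.44),
    pupa = c(3.90, 4.08, 3.98, 4.16),
    preadult = c(12.01, 13.74, 13.13, 13.59),
    adult_female = c(13.27, 8.00, 8.07, 10.50),
    adult_male = c(16.60, 9.21, 9.19, 11.07),
    adult_all = c(14.82, 8.49, 8.66, 10.75),
    longevity_all = c(21.36, 11.97, 13.27, 14.94),
    APOP = c(0.00, 0.53, 0.19, 0.17),
    TPOP = c(11.98, 13.83, 13.33, 13.83),
    oviposition_days = c(4.93, 3.26, 4.07, 4.60),
    fecundity = c(151.9, 75.95, 88.04, 92.29),
    r = c(0.29, 0.16, 0.20, 0.21),
    R0 = c(54.43, 12.03, 19.81, 26.92),
    T = c(13.68, 15.84, 14.94, 15.70),
    lambda = c(1.34, 1.18, 1.22, 1.23),
    stringsAsFactors = FALSE
  )
}

#' Construct a strain preset for the cohort simulator
#'
#' A preset fixes the stochastic world that [simulate_cohort()] draws from:
#' mean stage durations, per-stage preadult survival probabilities, sex
#' ratio, sex-specific adult longevity, the adult pre-oviposition period,
#' the number of oviposition days and the per-female total fecundity with
#' its negative-binomial dispersion.
#'
#' @param name preset label.
#' @param stage_duration_means named numeric, mean duration (days, > 0) per
#'   preadult stage, in developmental order.
#' @param stage_survival named numeric in \[0, 1\], probability of surviving
#'   each preadult stage (same names/order as `stage_duration_means`).
#' @param sex_ratio probability that a surviving individual is female.
#' @param adult_longevity_means named numeric `c(female = , male = )`, mean
#'   adult lifespan in days (>= 1).
#' @param apop_mean mean adult pre-oviposition period, days (>= 0).
#' @param oviposition_days_mean mean number of days with oviposition (>= 1).
#' @param total_fecundity_mean mean lifetime eggs per female.
#' @param fecundity_dispersion negative-binomial size parameter; larger is
#'   less overdispersed. Default 10, which reproduces the published
#'   standard errors of fecundity at n0 = 120 (coefficient of variation
#'   around 0.33).
#' @return object of class `strain_preset`.
#' @seealso [preset_from_table()] for the packaged calibrated presets.
#' @export
strain_preset <- function(name,
                          stage_duration_means,
                          stage_survival,
                          sex_ratio = 0.5,
                          adult_longevity_means,
                          apop_mean = 0,
                          oviposition_days_mean = 5,
                          total_fecundity_mean = 150,
                          fecundity_dispersion = 10) {
  stopifnot(
    length(stage_duration_means) >= 1,
    all(stage_duration_means > 0),
    length(stage_survival) == length(stage_duration_means),
    all(stage_survival >= 0), all(stage_survival <= 1),
    sex_ratio >= 0, sex_ratio <= 1,
    all(c("female", "male") %in% names(adult_longevity_means)),
    all(adult_longevity_means >= 1),
    apop_mean >= 0,
    oviposition_days_mean >= 1,
    total_fecundity_mean >= 0,
    fecundity_dispersion > 0
  )
  if (is.null(names(stage_survival))) {
    names(stage_survival) <- names(stage_duration_means)
  }
  structure(
    list(name = name,
         stage_duration_means = stage_duration_means,
         stage_survival = stage_survival,
         sex_ratio = sex_ratio,
         adult_longevity_means = adult_longevity_means,
         apop_mean = apop_mean,
         oviposition_days_mean = oviposition_days_mean,
         total_fecundity_mean = total_fecundity_mean,
         fecundity_dispersion = fecundity_dispersion),
    class = "strain_preset"
  )
}

#' Calibrated preset for a published strain
#'
#' Builds a [strain_preset()] from the published strain means (see
#' [strain_reference_values()]). Stage-duration, longevity, pre-oviposition
#' and fecundity means are transcribed directly. Survivorship percentages
#' were not published, so overall preadult survival is implied by the
#' identity R0 = fecundity x P(newborn becomes a reproducing female):
#' P(female adult) = R0 / fecundity, divided by the 0.5 sex ratio to give
#' overall preadult survival, split evenly across the three preadult
#' stages. For WT this gives P(female adult) = 54.43 / 151.9 = 0.358.
#'
#' @param strain_name one of `"WT"`, `"MU-1"`, `"MU-2"`, `"MU+14"`.
#' @param fecundity_dispersion negative-binomial size, see [strain_preset()].
#' @return a `strain_preset`.
#' @export
#' @examples
#' preset_from_table("WT")$total_fecundity_mean # 151.9
preset_from_table <- function(strain_name, fecundity_dispersion = 10) {
  tab <- strain_reference_values()
  k <- match(strain_name, tab$strain)
  if (is.na(k)) {
    stop("unknown strain '", strain_name, "'; available: ",
         paste(tab$strain, collapse = ", "), call. = FALSE)
  }
  row <- tab[k, ]
  p_female_adult <- row$R0 / row$fecundity
  sex_ratio <- 0.5
  preadult_survival <- p_female_adult / sex_ratio
  per_stage <- preadult_survival^(1 / 3)
  strain_preset(
    name = row$strain,
    stage_duration_means = c(egg = row$egg, larva = row$larva,
                             pupa = row$pupa),
    stage_survival = c(egg = per_stage, larva = per_stage,
                       pupa = per_stage),
    sex_ratio = sex_ratio,
    adult_longevity_means = c(female = row$adult_female,
                              male = row$adult_male),
    apop_mean = row$APOP,
    oviposition_days_mean = row$oviposition_days,
    total_fecundity_mean = row$fecundity,
    fecundity_dispersion = fecundity_dispersion
  )
}

#' @export
print.strain_preset <- function(x, ...) {
  cat("<strain_preset> ", x$name, "\n", sep = "")
  cat("  stage means (d): ",
      paste(names(x$stage_duration_means),
            format(x$stage_duration_means, digits = 3), collapse = ", "),
      "\n", sep = "")
  cat("  stage survival: ",
      paste(format(x$stage_survival, digits = 3), collapse = ", "),
      "  sex ratio: ", x$sex_ratio, "\n", sep = "")
  cat("  adult longevity (d): F ", x$adult_longevity_means[["female"]],
      ", M ", x$adult_longevity_means[["male"]], "\n", sep = "")
  cat("  fecundity: ", x$total_fecundity_mean, " eggs (NB size ",
      x$fecundity_dispersion, "), APOP ", x$apop_mean, " d, ",
      x$oviposition_days_mean, " oviposition d\n", sep = "")
  invisible(x)
}
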