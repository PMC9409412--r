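#' Simulation configuration
#'
#' @param n0 cohort size (number of eggs followed; published design: 120).
#' @param seed integer RNG seed; the seed fully determines the cohort.
#' @param duration_distribution `"shifted_poisson"` (default; duration =
#'   1 + Poisson(mean - 1), integer days >= 1), `"discretized_gamma"`
#'   (ceiling of a Gamma with shape `gamma_shape`, same mean) or
#'   `"deterministic"` (every duration = round(mean), for degenerate
#'   test worlds).
#' @param fecundity_allocation currently only `"geometric_decay"`: a
#'   female's total eggs are spread over her oviposition days with
#'   geometrically decaying expected shares (early-peaked daily schedule).
#' @param geometric_q decay ratio of the daily oviposition shares.
#' @param gamma_shape shape for the discretized-gamma family.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n0 = 120, seed = 1,
                              duration_distribution = c("shifted_poisson",
                                                        "discretized_gamma",
                                                        "deterministic"),
                              fecundity_allocation = "geometric_decay",
                              geometric_q = 0.65,
                              gamma_shape = 20) {
  duration_distribution <- match.arg(duration_distribution)
  if (!identical(fecundity_allocation, "geometric_decay")) {
    stop("config error: unknown fecundity_allocation '",
         fecundity_allocation, "'", call. = FALSE)
  }
  stopifnot(n0 >= 1, geometric_q > 0, geometric_q <= 1, gamma_shape > 0)
  structure(
    list(n0 = as.integer(n0), seed = as.integer(seed),
         duration_distribution = duration_distribution,
         fecundity_allocation = fecundity_allocation,
         geometric_q = geometric_q, gamma_shape = gamma_shape),
    class = "simulation_config"
  )
}

# integer stage duration >= 1 with the requested mean
draw_duration <- function(n, mean, config) {
  switch(config$duration_distribution,
         shifted_poisson = 1L + stats::rpois(n, max(mean - 1, 0)),
         deterministic = rep(max(1L, as.integer(round(mean))), n),
         discretized_gamma = {
           # ceiling(Gamma) with mean matched: E[ceil(X)] ~ E[X] + 1/2
           sh <- config$gamma_shape
           m <- max(mean - 0.5, 0.51)
           pmax(1L, as.integer(ceiling(stats::rgamma(n, shape = sh,
                                                     rate = sh / m))))
         })
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Simulate an individual-level cohort
#'
#' Draws a full synthetic cohort under a [strain_preset()]: each of the
#' `n0` eggs passes through the preadult stages with integer stage
#' durations and per-stage survival; survivors are sexed at the preset sex
#' ratio, live an adult lifespan drawn by sex, and females receive a
#' negative-binomial lifetime fecundity laid out over an early-peaked
#' daily schedule starting after the adult pre-oviposition period.
#' Individuals dying in the egg or larva are recorded with `sex =
#' "unknown"` (sexing happens at pupation); pupal deaths keep their sex.
#' The RNG state of the session is preserved; the seed in `config` fully
#' determines the output.
#'
#' @param preset a `strain_preset`.
#' @param config a `simulation_config`.
#' @return a validated [cohort_table()].
#' @export
#' @examples
#' co <- simulate_cohort(preset_from_table("WT"), simulation_config(seed = 7))
#' co
simulate_cohort <- function(preset, config = simulation_config()) {
  stopifnot(inherits(preset, "strain_preset"))
  if (!inherits(config, "simulation_config")) {
    stop("config error: `config` must be a simulation_config", call. = FALSE)
  }
  with_preserved_rng(config$seed, simulate_cohort_impl(preset, config))
}

simulate_cohort_impl <- function(preset, config) {
  n0 <- config$n0
  pre <- names(preset$stage_duration_means)
  n_pre <- length(pre)
  stage_order <- c(pre, "female", "male")
  unsexed <- pre[pre %in% c("egg", "larva") | grepl("^L[0-9]+$", pre)]

  ids <- sprintf("%s-%03d", preset$name, seq_len(n0))
  sex_true <- ifelse(stats::runif(n0) < preset$sex_ratio, "female", "male")

  dur <- matrix(NA_integer_, nrow = n0, ncol = n_pre,
                dimnames = list(NULL, paste0("dur_", pre)))
  full_dur <- sapply(seq_len(n_pre), function(j) {
    draw_duration(n0, preset$stage_duration_means[j], config)
  })
  if (n0 == 1) full_dur <- matrix(full_dur, nrow = 1)
  survives <- sapply(seq_len(n_pre), function(j) {
    stats::runif(n0) < preset$stage_survival[j]
  })
  if (n0 == 1) survives <- matrix(survives, nrow = 1)

  sex <- character(n0)
  fate <- character(n0)
  death_stage <- character(n0)
  emergence <- rep(NA_integer_, n0)
  death_day <- integer(n0)
  fec_id <- list(); fec_age <- list(); fec_eggs <- list()

  for (i in seq_len(n0)) {
    died_at <- which(!survives[i, ])
    if (length(died_at) > 0) {
      j <- died_at[1]
      done <- if (j > 1) full_dur[i, seq_len(j - 1)] else integer(0)
      if (j > 1) dur[i, seq_len(j - 1)] <- done
      # dies after 1..D_j days censused in the death stage
      partial <- sample.int(full_dur[i, j], 1)
      fate[i] <- "died_preadult"
      death_stage[i] <- pre[j]
      death_day[i] <- sum(done) + partial
      sex[i] <- if (pre[j] %in% unsexed) "unknown" else sex_true[i]
      next
    }
    dur[i, ] <- full_dur[i, ]
    em <- sum(full_dur[i, ])
    emergence[i] <- em
    sex[i] <- sex_true[i]
    fate[i] <- "died_adult"
    death_stage[i] <- if (sex[i] == "female") "female" else "male"
    longevity <- draw_duration(
      1, preset$adult_longevity_means[[sex[i]]], config)
    death_day[i] <- em + longevity

    if (sex[i] == "female") {
      total <- stats::rnbinom(1, size = preset$fecundity_dispersion,
                              mu = preset$total_fecundity_mean)
      apop <- stats::rpois(1, preset$apop_mean)
      first <- em + apop
      if (total > 0 && first < death_day[i]) {
        avail <- death_day[i] - first      # days first .. death_day-1
        ndays <- min(avail,
                     1L + stats::rpois(1,
                                       max(preset$oviposition_days_mean - 1,
                                           0)))
        w <- config$geometric_q^(seq_len(ndays) - 1)
        eggs <- as.integer(stats::rmultinom(1, total, w))
        keep <- eggs > 0
        if (any(keep)) {
          fec_id[[length(fec_id) + 1]] <- rep(ids[i], sum(keep))
          fec_age[[length(fec_age) + 1]] <- (first + seq_len(ndays) -
                                               1L)[keep]
          fec_eggs[[length(fec_eggs) + 1]] <- eggs[keep]
        }
      }
    }
  }

  ind <- data.frame(id = ids, sex = sex, fate = fate,
                    death_stage = death_stage,
                    emergence_day = emergence, death_day = death_day,
                    stringsAsFactors = FALSE)
  ind <- cbind(ind, as.data.frame(dur))
  fec <- data.frame(id = unlist(c(fec_id, list(character(0)))),
                    age_day = as.integer(unlist(c(fec_age, list(integer(0))))),
                    eggs = as.integer(unlist(c(fec_eggs, list(integer(0))))),
                    stringsAsFactors = FALSE)
  cohort_table(ind, fec, stage_order = stage_order,
               strain_label = preset$name)
}
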