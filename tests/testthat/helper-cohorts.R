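# Shared fixtures, built in code.

# Four-individual toy cohort used across the life-table oracle tests:
#   A: female, egg 2 / larva 3 / pupa 2, emerges day 7, dies day 10,
#      lays 4 eggs on day 7 and 6 eggs on day 8
#   B: female, egg 2 / larva 3 / pupa 3, emerges day 8, dies day 10, no eggs
#   C: male,   egg 2 / larva 4 / pupa 2, emerges day 8, dies day 12
#   D: dies unsexed in the larva after 1 day (death day 3)
toy_cohort <- function() {
  ind <- data.frame(
    id = c("A", "B", "C", "D"),
    sex = c("female", "female", "male", "unknown"),
    fate = c("died_adult", "died_adult", "died_adult", "died_preadult"),
    death_stage = c("female", "female", "male", "larva"),
    emergence_day = c(7L, 8L, 8L, NA),
    death_day = c(10L, 10L, 12L, 3L),
    dur_egg = c(2L, 2L, 2L, 2L),
    dur_larva = c(3L, 3L, 4L, NA),
    dur_pupa = c(2L, 3L, 2L, NA),
    stringsAsFactors = FALSE
  )
  fec <- data.frame(id = c("A", "A"), age_day = c(7L, 8L),
                    eggs = c(4L, 6L), stringsAsFactors = FALSE)
  cohort_table(ind, fec, strain_label = "toy")
}

# Hand-tabulated daily census of toy_cohort(): fractions of n0 = 4 alive
# and in each stage at ages 0..11 (columns egg, larva, pupa, female, male).
toy_S_oracle <- function() {
  m <- rbind(
    c(1.00, 0.00, 0.00, 0.00, 0.00),  # age 0: all 4 eggs
    c(1.00, 0.00, 0.00, 0.00, 0.00),  # age 1
    c(0.00, 1.00, 0.00, 0.00, 0.00),  # age 2: all larvae (D's only day)
    c(0.00, 0.75, 0.00, 0.00, 0.00),  # age 3: D dead
    c(0.00, 0.75, 0.00, 0.00, 0.00),  # age 4
    c(0.00, 0.25, 0.50, 0.00, 0.00),  # age 5: A,B pupae; C larva
    c(0.00, 0.00, 0.75, 0.00, 0.00),  # age 6
    c(0.00, 0.00, 0.50, 0.25, 0.00),  # age 7: A emerged
    c(0.00, 0.00, 0.00, 0.50, 0.25),  # age 8: B, C emerged
    c(0.00, 0.00, 0.00, 0.50, 0.25),  # age 9
    c(0.00, 0.00, 0.00, 0.00, 0.25),  # age 10: only C
    c(0.00, 0.00, 0.00, 0.00, 0.25)   # age 11
  )
  dimnames(m) <- list(age = 0:11,
                      stage = c("egg", "larva", "pupa", "female", "male"))
  m
}

toy_lx_oracle <- function() {
  c(1, 1, 1, 0.75, 0.75, 0.75, 0.75, 0.75, 0.75, 0.75, 0.25, 0.25)
}

# mx: eggs per survivor at each age. Age 7: 4 eggs / (0.75 * 4 alive);
# age 8: 6 eggs / (0.75 * 4 alive).
toy_mx_oracle <- function() {
  mx <- rep(0, 12)
  mx[8] <- (0.25 * 4) / 0.75   # age 7
  mx[9] <- (0.50 * 3) / 0.75   # age 8: 2 females alive, 3 eggs each
  mx
}

# Brute-force Euler-Lotka: 1e-6-step grid search for the r minimizing
# |sum exp(-r (x+1)) phi - 1|, independent of the package solver.
grid_search_r <- function(ages, phi, lo = -0.5, hi = 1, step = 1e-6) {
  r <- seq(lo, hi, by = step)
  lhs <- vapply(r, function(rr) sum(exp(-rr * (ages + 1)) * phi),
                numeric(1))
  r[which.min(abs(lhs - 1))]
}

fecundity_path_for_test <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "_fecundity\\1", path)
}

# Deterministic degenerate world: survival 1, durations (3, 5, 4) fixed.
deterministic_preset <- function(fecundity = 0) {
  strain_preset(
    name = "degenerate",
    stage_duration_means = c(egg = 3, larva = 5, pupa = 4),
    stage_survival = c(egg = 1, larva = 1, pupa = 1),
    adult_longevity_means = c(female = 5, male = 5),
    apop_mean = 0,
    oviposition_days_mean = 2,
    total_fecundity_mean = fecundity
  )
}
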