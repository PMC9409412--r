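test_that("single deterministic record: census convention", {
  ind <- data.frame(
    id = "x", sex = "female", fate = "died_adult", death_stage = "female",
    emergence_day = 12L, death_day = 14L,
    dur_egg = 3L, dur_larva = 5L, dur_pupa = 4L, stringsAsFactors = FALSE
  )
  asm <- compute_age_stage(cohort_table(ind))
  expect_identical(asm$ages, 0:13)
  # exactly one unit entry per age
  expect_equal(unname(rowSums(asm$S)), rep(1, 14))
  occupied <- unname(apply(asm$S, 1, function(r) asm$stages[which(r == 1)]))
  expect_equal(occupied,
               c(rep("egg", 3), rep("larva", 5), rep("pupa", 4),
                 rep("female", 2)))
})

test_that("all dying in the egg on day 1 empties the census from age 1", {
  ind <- data.frame(
    id = c("a", "b"), sex = "unknown", fate = "died_preadult",
    death_stage = "egg", emergence_day = NA_integer_, death_day = 1L,
    dur_egg = NA_integer_, dur_larva = NA_integer_,
    dur_pupa = NA_integer_, stringsAsFactors = FALSE
  )
  asm <- compute_age_stage(cohort_table(ind))
  expect_equal(sum(asm$S[1, ]), 1)
  expect_identical(nrow(asm$S), 1L)  # no one alive at age >= 1
  cur <- compute_curves(asm)
  expect_equal(cur$lx[1], 1)
  expect_equal(compute_R0(cur), 0)
})

test_that("toy cohort matches the hand-tabulated census oracle", {
  co <- toy_cohort()
  asm <- compute_age_stage(co)
  expect_equal(unclass(asm$S), toy_S_oracle(), ignore_attr = TRUE)

  cur <- compute_curves(asm)
  expect_equal(cur$lx, toy_lx_oracle())
  expect_equal(cur$mx, toy_mx_oracle())

  # R0 = sum lx mx = 1.0 + 1.5 = 2.5 = 10 eggs / n0 4
  expect_equal(compute_R0(cur), 2.5)

  # fx (eggs per living female): 4 on day 7 (1 female), 3 on day 8 (2)
  expect_equal(cur$fx_female[8:9], c(4, 3))
})

test_that("toy cohort summaries equal hand computation", {
  s <- summarize_cohort(toy_cohort())
  get <- function(m, f = "mean") s[s$metric == m, f]
  expect_equal(get("egg"), 2)
  expect_equal(get("egg", "sd"), 0)
  expect_equal(get("larva"), 10 / 3)
  expect_equal(get("larva", "n"), 3)
  expect_equal(get("pupa"), 7 / 3)
  expect_equal(get("preadult"), 23 / 3)
  expect_equal(get("adult_female"), 2.5)
  expect_equal(get("adult_male"), 4)
  expect_equal(get("adult_all"), 3)
  expect_equal(get("longevity_all"), 8.75)
  expect_equal(get("longevity_all", "n"), 4)
  expect_equal(get("APOP"), 0)
  expect_equal(get("TPOP"), 7)
  expect_equal(get("oviposition_days"), 2)
  expect_equal(get("fecundity"), 5)   # (10 + 0) / 2 females
  expect_equal(get("fecundity", "n"), 2)
})

test_that("solve_r: closed-form single-age schedules", {
  mk <- function(ages, phi) {
    structure(list(ages = ages, lx = rep(1, length(ages)), mx = phi,
                   product = phi, fx_female = phi),
              class = "life_table_curves")
  }
  # all mass 4.0 at age 9: exp(-10 r) * 4 = 1
  cur <- mk(0:9, c(rep(0, 9), 4))
  expect_equal(solve_r(cur), log(4) / 10, tolerance = 1e-9)
  # mass 1.0 at a single age -> r = 0 (any age)
  for (age in c(3, 9, 17)) {
    cur <- mk(0:age, c(rep(0, age), 1))
    expect_equal(solve_r(cur), 0)
    # T by continuity = x + 1
    expect_equal(finalize_parameters(cur, 0)$T, age + 1)
  }
  # R0 = 0 is an undefined-parameter error
  expect_error(solve_r(mk(0:5, rep(0, 6))), "R0 = 0")
})

test_that("solve_r matches a 1e-6 grid search on two-age schedules", {
  # the spec's fixed example {x=5: 2.0, x=8: 1.5} ...
  ages <- 0:8
  phi <- rep(0, 9); phi[6] <- 2.0; phi[9] <- 1.5
  cur <- structure(list(ages = ages, product = phi),
                   class = "life_table_curves")
  expect_lt(abs(solve_r(cur) - grid_search_r(ages, phi)), 1e-6)

  # ... and random two-age schedules
  set.seed(42)
  for (k in 1:8) {
    x <- sort(sample(1:25, 2))
    mass <- round(stats::runif(2, 0.2, 3), 2)
    phi <- rep(0, x[2] + 1)
    phi[x + 1] <- mass
    cur <- structure(list(ages = 0:x[2], product = phi),
                     class = "life_table_curves")
    r <- solve_r(cur)
    expect_lt(abs(r - grid_search_r(0:x[2], phi)), 1e-6)
    # residual within solver tolerance
    expect_lt(abs(sum(exp(-r * (0:x[2] + 1)) * phi) - 1), 1e-10)
  }
})

test_that("consistency triple holds exactly on simulated cohorts", {
  for (seed in c(2, 5, 8)) {
    co <- simulate_cohort(preset_from_table("WT"),
                          simulation_config(n0 = 80, seed = seed))
    lt <- life_table(co)
    p <- lt$params
    expect_identical(p$lambda, exp(p$r))
    expect_identical(p$T, log(p$R0) / p$r)
    expect_lt(p$euler_residual, 1e-10)
    # R0 identity: total eggs / n0, exact
    expect_equal(p$R0, sum(co$fecundity$eggs) / co$n0)
  }
})

test_that("Leslie projection growth factor converges to lambda", {
  # independent oracle: age-classified daily projection built from
  # px = l(x+1)/lx and mx; its asymptotic growth factor must equal
  # exp(r) from the Euler-Lotka solver
  for (seed in 1:10) {
    co <- simulate_cohort(preset_from_table(c("WT", "MU-2")[seed %% 2 + 1]),
                          simulation_config(n0 = 100, seed = seed))
    lt <- life_table(co)
    lx <- lt$curves$lx
    mx <- lt$curves$mx
    n_age <- length(lx)
    L <- matrix(0, n_age, n_age)
    L[1, ] <- mx
    px <- ifelse(lx[-n_age] > 0, lx[-1] / lx[-n_age], 0)
    L[cbind(2:n_age, 1:(n_age - 1))] <- px
    v <- rep(1, n_age)
    growth <- NA
    for (it in 1:500) {
      v2 <- L %*% v
      growth <- sum(v2) / sum(v)
      v <- v2 / sum(v2)
    }
    expect_equal(growth, lt$params$lambda, tolerance = 1e-4)
  }
})

test_that("monotonicity: deaths never raise lx; removing eggs never raises R0", {
  co <- simulate_cohort(preset_from_table("WT"),
                        simulation_config(n0 = 60, seed = 31))
  lt <- life_table(co)
  expect_true(all(diff(lt$curves$lx) <= 1e-12))

  # kill one adult earlier
  ind <- co$individuals
  k <- which(ind$fate == "died_adult")[1]
  ind$death_day[k] <- ind$emergence_day[k] + 1L
  fec <- co$fecundity
  fec <- fec[!(fec$id == ind$id[k] & fec$age_day >= ind$death_day[k]), ]
  co2 <- cohort_table(ind, fec, co$stage_order, co$strain_label)
  lt2 <- life_table(co2)
  n <- min(length(lt$curves$lx), length(lt2$curves$lx))
  expect_true(all(lt2$curves$lx[1:n] <= lt$curves$lx[1:n] + 1e-12))

  # remove a female's eggs entirely
  fec3 <- co$fecundity[co$fecundity$id != co$fecundity$id[1], ]
  co3 <- cohort_table(co$individuals, fec3, co$stage_order)
  expect_lt(compute_R0(compute_curves(compute_age_stage(co3))),
            lt$params$R0)
})

test_that("export_curves round-trips and lx is monotone in the file", {
  co <- toy_cohort()
  lt <- life_table(co)
  prefix <- file.path(withr::local_tempdir(), "toy")
  paths <- export_curves(lt$asm, lt$curves, prefix)
  sxj <- utils::read.csv(paths[1])
  curves <- utils::read.csv(paths[2])
  expect_equal(nrow(sxj), length(lt$asm$ages) * length(lt$asm$stages))
  back <- matrix(sxj$Sxj, nrow = length(lt$asm$ages))
  expect_equal(back, unname(lt$asm$S))
  expect_equal(curves$lx, lt$curves$lx)
  expect_equal(curves$mx, lt$curves$mx)
  expect_true(all(diff(curves$lx) <= 0))
})
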