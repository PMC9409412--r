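make_tiny_cohort <- function(durations) {
  # adults with distinct preadult durations, one egg day each so r is
  # defined; larva/pupa fixed at 1 day each
  n <- length(durations)
  egg <- durations - 2L
  ind <- data.frame(
    id = paste0("i", seq_len(n)), sex = "female", fate = "died_adult",
    death_stage = "female", emergence_day = durations,
    death_day = durations + 2L, dur_egg = egg, dur_larva = 1L,
    dur_pupa = 1L, stringsAsFactors = FALSE
  )
  fec <- data.frame(id = ind$id, age_day = durations, eggs = 10L,
                    stringsAsFactors = FALSE)
  cohort_table(ind, fec)
}

test_that("identical individuals give SE = 0 for duration metrics", {
  co <- make_tiny_cohort(c(8L, 8L, 8L))
  br <- bootstrap_parameters(co, bootstrap_config(B = 50, seed = 1))
  for (p in c("egg", "larva", "pupa", "preadult", "longevity_all",
              "fecundity", "R0")) {
    expect_equal(unname(br$se[p]), 0)
  }
  expect_identical(br$n_degenerate, 0L)
})

test_that("exhaustive bootstrap at n = 3 equals the enumeration oracle", {
  co <- make_tiny_cohort(c(6L, 9L, 12L))
  br <- bootstrap_parameters(co, bootstrap_config(B = 1, seed = 1,
                                                  exhaustive = TRUE))
  expect_identical(nrow(br$resamples), 27L)

  # independent oracle: all 3^3 ordered with-replacement resamples
  grid <- expand.grid(1:3, 1:3, 1:3)
  pre <- c(6, 9, 12)
  means <- apply(grid, 1, function(g) mean(pre[unlist(g)]))
  oracle_se <- sqrt(mean((means - mean(means))^2))
  expect_equal(unname(br$se["preadult"]), oracle_se)
  expect_equal(unname(br$boot_mean["preadult"]), mean(means))
  expect_equal(unname(br$point["preadult"]), 9)

  # R0 over resamples: total eggs / 3 is constant (10 each), SE = 0
  expect_equal(unname(br$se["R0"]), 0)

  # r varies with the resampled timing; check one resample directly:
  # resample (1,1,1) has all mass 30/3 = 10 eggs/newborn at age 6
  ind3 <- co$individuals[c(1, 1, 1), ]
  ind3$id <- c("a", "b", "c")
  sub <- cohort_table(ind3,
                      data.frame(id = c("a", "b", "c"), age_day = 6L,
                                 eggs = 10L))
  expect_equal(life_table(sub)$params$r, log(10) / 7, tolerance = 1e-9)
})

test_that("bootstrap fast path agrees with the full life-table engine", {
  co <- simulate_cohort(preset_from_table("MU-2"),
                        simulation_config(n0 = 60, seed = 17))
  br <- bootstrap_parameters(co, bootstrap_config(B = 2, seed = 1))
  lt <- life_table(co)
  s <- lt$summaries
  expect_equal(unname(br$point["r"]), lt$params$r)
  expect_equal(unname(br$point["R0"]), lt$params$R0)
  expect_equal(unname(br$point["T"]), lt$params$T)
  for (m in s$metric) {
    expect_equal(unname(br$point[m]), s[s$metric == m, "mean"],
                 info = m)
  }
})

test_that("seed determinism and Monte-Carlo stability of SEs", {
  co <- simulate_cohort(preset_from_table("WT"),
                        simulation_config(n0 = 120, seed = 4))
  b1 <- bootstrap_parameters(co, bootstrap_config(B = 400, seed = 10))
  b2 <- bootstrap_parameters(co, bootstrap_config(B = 400, seed = 10))
  expect_identical(b1$resamples, b2$resamples)

  # two seeds at B = 2000: SEs agree within 10% relative
  b3 <- bootstrap_parameters(co, bootstrap_config(B = 2000, seed = 1))
  b4 <- bootstrap_parameters(co, bootstrap_config(B = 2000, seed = 2))
  for (p in c("r", "R0", "T", "fecundity", "preadult")) {
    expect_lt(abs(b3$se[p] - b4$se[p]) / b3$se[p], 0.10)
  }
})

test_that("SE scales ~ 1/sqrt(n0)", {
  sizes <- c(50L, 100L, 200L, 400L, 800L)
  ses <- vapply(sizes, function(n0) {
    co <- simulate_cohort(preset_from_table("WT"),
                          simulation_config(n0 = n0, seed = 1000 + n0))
    br <- bootstrap_parameters(co, bootstrap_config(B = 300, seed = 1))
    unname(br$se["fecundity"])
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(ses) ~ log(sizes)))[2]
  expect_gt(slope, -0.65)
  expect_lt(slope, -0.35)
})

test_that("degenerate resamples follow the policy", {
  # 1 reproducing female among 4 individuals: many resamples lack her
  ind <- data.frame(
    id = c("f", "m1", "m2", "m3"),
    sex = c("female", "male", "male", "male"),
    fate = "died_adult",
    death_stage = c("female", "male", "male", "male"),
    emergence_day = 6L, death_day = 9L,
    dur_egg = 2L, dur_larva = 2L, dur_pupa = 2L, stringsAsFactors = FALSE
  )
  fec <- data.frame(id = "f", age_day = 6L, eggs = 12L)
  co <- cohort_table(ind, fec)

  br <- bootstrap_parameters(co, bootstrap_config(B = 200, seed = 3))
  expect_gt(br$n_degenerate, 0)
  expect_identical(sum(is.na(br$resamples[, "r"])), br$n_degenerate)
  expect_false(anyNA(br$resamples[, "R0"]))

  br2 <- bootstrap_parameters(
    co, bootstrap_config(B = 200, seed = 3, degenerate_policy = "redraw"))
  expect_identical(br2$n_degenerate, 0L)
})

test_that("paired test: a cohort against itself is p = 1", {
  co <- simulate_cohort(preset_from_table("WT"),
                        simulation_config(n0 = 50, seed = 6))
  res <- paired_bootstrap_test(co, co, bootstrap_config(B = 100, seed = 2))
  expect_true(all(res$mean_difference == 0))
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))
})

test_that("paired test p-value equals the brute-force tail fraction", {
  a <- make_tiny_cohort(c(6L, 9L, 12L))
  b <- make_tiny_cohort(c(7L, 8L, 13L))
  cfg <- bootstrap_config(B = 500, seed = 11)
  res <- paired_bootstrap_test(a, b, cfg, parameters = "preadult")

  # oracle: replay the resampling with the same seeded stream and apply
  # the two-sided tail-fraction definition directly
  draw <- function(seed, n0, B) {
    set.seed(seed)
    matrix(sample.int(n0, n0 * B, replace = TRUE), nrow = B)
  }
  ia <- draw(11, 3, 500)
  ib <- draw(11, 3, 500)
  pa <- c(6, 9, 12); pb <- c(7, 8, 13)
  d <- vapply(1:500, function(k) {
    mean(pa[ia[k, ]]) - mean(pb[ib[k, ]])
  }, numeric(1))
  p_oracle <- max(2 * min(sum(d < 0), sum(d > 0)) / 500, 1 / 500)
  expect_equal(res$p_value, min(p_oracle, 1))
})

test_that("strains with 4-fold R0 difference are detected", {
  wt <- simulate_cohort(preset_from_table("WT"),
                        simulation_config(n0 = 120, seed = 1))
  mu <- simulate_cohort(preset_from_table("MU-1"),
                        simulation_config(n0 = 120, seed = 2))
  res <- paired_bootstrap_test(wt, mu, bootstrap_config(B = 2000, seed = 5))
  r0 <- res[res$parameter == "R0", ]
  expect_gt(r0$mean_difference, 0)
  expect_lt(r0$p_value, 0.05)
  expect_true(r0$significant)
})
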