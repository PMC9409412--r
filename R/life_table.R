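#' Age-stage survival and fecundity matrices
#'
#' Tabulates the daily census of a cohort into the age-stage survival
#' matrix S (entry S\[x, j\] = fraction of the n0 newborns alive and in
#' stage j at age x days) and the age-stage fecundity matrix F (mean eggs
#' laid at age x per living female adult; nonzero only in the female-adult
#' column). An individual is counted in a stage on the first day of that
#' stage, and alive at every age strictly before its death day.
#'
#' @param cohort a [cohort_table()].
#' @return object of class `age_stage_matrix`: list with `ages`
#'   (0..x_max), `stages`, matrices `S` and `F` (rows = ages), and `n0`.
#' @export
compute_age_stage <- function(cohort) {
  validate_cohort(cohort)
  ind <- cohort$individuals
  so <- cohort$stage_order
  pre <- preadult_stages(so)
  n0 <- cohort$n0
  x_max <- max(ind$death_day) - 1L
  ages <- 0:x_max

  S <- matrix(0, nrow = x_max + 1L, ncol = length(so),
              dimnames = list(age = ages, stage = so))
  for (k in seq_len(nrow(ind))) {
    r <- ind[k, ]
    durs <- unlist(r[paste0("dur_", pre)])
    stages_k <- character(0)
    lens_k <- integer(0)
    if (r$fate == "died_adult") {
      stages_k <- c(pre, r$death_stage)
      lens_k <- c(durs, r$death_day - r$emergence_day)
    } else {
      j <- match(r$death_stage, pre)
      done <- if (j > 1) durs[seq_len(j - 1)] else integer(0)
      partial <- r$death_day - sum(done)
      stages_k <- pre[seq_len(j)]
      lens_k <- c(done, partial)
    }
    start <- 0L
    for (s in seq_along(stages_k)) {
      len <- lens_k[s]
      if (len > 0) {
        rows <- seq.int(start, start + len - 1L) + 1L
        col <- match(stages_k[s], so)
        S[rows, col] <- S[rows, col] + 1
      }
      start <- start + len
    }
  }
  S <- S / n0

  FF <- matrix(0, nrow = x_max + 1L, ncol = length(so),
               dimnames = dimnames(S))
  fec <- cohort$fecundity
  if (nrow(fec) > 0) {
    fcol <- match(adult_stages(so)[1], so)
    eggs_by_age <- tapply(fec$eggs, factor(fec$age_day, levels = ages),
                          sum, default = 0)
    females_alive <- S[, fcol] * n0
    nz <- which(eggs_by_age > 0)
    FF[nz, fcol] <- eggs_by_age[nz] / females_alive[nz]
  }

  structure(list(ages = ages, stages = so, S = S, F = FF, n0 = n0),
            class = "age_stage_matrix")
}

#' Age-specific survival and fecundity curves
#'
#' Collapses an age-stage matrix into the classical age-indexed curves:
#' survival l_x = sum over stages of S\[x, j\]; population age-specific
#' fecundity m_x = sum_j S\[x, j\] f\[x, j\] / sum_j S\[x, j\] (the mean
#' daily egg output per survivor of age x, weighted by stage composition),
#' defined as 0 at ages with no survivors; and their product l_x m_x, the
#' per-newborn reproductive value realised at age x.
#'
#' @param asm an `age_stage_matrix`.
#' @return object of class `life_table_curves`: list with `ages`, `lx`,
#'   `mx`, `product` and `fx_female` (eggs per living female at each age).
#' @export
compute_curves <- function(asm) {
  stopifnot(inherits(asm, "age_stage_matrix"))
  lx <- rowSums(asm$S)
  num <- rowSums(asm$S * asm$F)
  mx <- ifelse(lx > 0, num / lx, 0)
  fcol <- match(adult_stages(asm$stages)[1], asm$stages)
  structure(list(ages = asm$ages, lx = unname(lx), mx = unname(mx),
                 product = unname(ifelse(lx > 0, num, 0)),
                 fx_female = unname(asm$F[, fcol])),
            class = "life_table_curves")
}

#' Net reproductive rate
#'
#' R0 = sum over ages of l_x m_x: the expected lifetime offspring per
#' newborn (both sexes counted in the denominator). Under the daily census
#' this equals (total eggs laid by the cohort) / n0 exactly.
#'
#' @param curves a `life_table_curves`.
#' @return nonnegative scalar.
#' @export
compute_R0 <- function(curves) {
  stopifnot(inherits(curves, "life_table_curves"))
  sum(curves$product)
}

# Euler-Lotka LHS minus 1 and its derivative in r, for schedule phi(x)
euler_fn <- function(r, ages, phi) {
  sum(exp(-r * (ages + 1)) * phi) - 1
}

# Solve sum_x exp(-r (x+1)) phi(x) = 1 for r given the schedule phi.
solve_r_schedule <- function(ages, phi, tol = 1e-10,
                             bracket = c(-1, 2)) {
  keep <- phi > 0
  ages <- ages[keep]
  phi <- phi[keep]
  R0 <- sum(phi)
  if (R0 <= 0) {
    stop("undefined parameter: r has no solution when R0 = 0",
         call. = FALSE)
  }
  tbar <- sum((ages + 1) * phi) / R0
  if (abs(R0 - 1) < 1e-14) {
    return(0)
  }
  # Newton from the Lotka approximation r0 = ln(R0)/Tbar, safeguarded by
  # the bracket (f is strictly decreasing in r)
  lo <- bracket[1]; hi <- bracket[2]
  while (euler_fn(lo, ages, phi) < 0) {
    lo <- lo - 1
    if (lo < -50) {
      stop("solver error: no bracket for r (schedule ",
           "mass too small even at r = -50)", call. = FALSE)
    }
  }
  if (euler_fn(hi, ages, phi) > 0) {
    stop("solver error: r exceeds the upper bracket ", hi,
         " (residual ", format(euler_fn(hi, ages, phi)), ")",
         call. = FALSE)
  }
  r <- min(max(log(R0) / tbar, lo), hi)
  for (iter in 1:100) {
    f <- euler_fn(r, ages, phi)
    if (abs(f) < tol) break
    if (f > 0) lo <- max(lo, r) else hi <- min(hi, r)
    fp <- -sum((ages + 1) * exp(-r * (ages + 1)) * phi)
    r_new <- r - f / fp
    if (!is.finite(r_new) || r_new <= lo || r_new >= hi) {
      r_new <- (lo + hi) / 2
    }
    r <- r_new
  }
  if (abs(euler_fn(r, ages, phi)) >= tol) {
    stop("solver error: Euler-Lotka residual ",
         format(abs(euler_fn(r, ages, phi))), " above tolerance ", tol,
         call. = FALSE)
  }
  r
}

#' Solve the Euler-Lotka equation for the intrinsic rate of increase
#'
#' Finds r such that sum_x exp(-r (x + 1)) l_x m_x = 1, the discrete
#' Euler-Lotka equation with ages starting at 0 (hence the x + 1
#' exponent; many texts index ages from 1 and write exp(-r x)). The left
#' side is strictly decreasing in r, so the root is unique; it is found by
#' safeguarded Newton iteration inside `bracket` (extended downward
#' automatically when R0 is very small) to residual `tol`. r > 0 iff
#' R0 > 1 and r = 0 iff R0 = 1.
#'
#' @param curves a `life_table_curves` with R0 > 0.
#' @param tol residual tolerance (default 1e-10).
#' @param bracket numeric length-2 search interval (default c(-1, 2) per
#'   day, generous for insect demography).
#' @return the intrinsic rate of increase r (per day).
#' @export
solve_r <- function(curves, tol = 1e-10, bracket = c(-1, 2)) {
  stopifnot(inherits(curves, "life_table_curves"))
  solve_r_schedule(curves$ages, curves$product, tol = tol,
                   bracket = bracket)
}

#' Assemble the population parameters
#'
#' Completes the parameter set from the solved intrinsic rate: finite rate
#' of increase lambda = exp(r) and mean generation time T = ln(R0) / r.
#' At r = 0 (R0 = 1) the ratio is 0/0 and T is defined by continuity as
#' the mean age of the l_x m_x distribution, sum (x + 1) l_x m_x / R0.
#'
#' @param curves a `life_table_curves`.
#' @param r solved intrinsic rate from [solve_r()].
#' @return object of class `population_parameters`: list with `R0`, `r`,
#'   `lambda`, `T` and `euler_residual`.
#' @export
finalize_parameters <- function(curves, r) {
  stopifnot(inherits(curves, "life_table_curves"))
  R0 <- compute_R0(curves)
  if (R0 <= 0) {
    stop("undefined parameter: R0 = 0", call. = FALSE)
  }
  T <- if (r == 0) {
    sum((curves$ages + 1) * curves$product) / R0
  } else {
    log(R0) / r
  }
  structure(list(R0 = R0, r = r, lambda = exp(r), T = T,
                 euler_residual = abs(euler_fn(r, curves$ages,
                                               curves$product))),
            class = "population_parameters")
}

#' @export
print.population_parameters <- function(x, ...) {
  cat(sprintf("r = %.4f /d   R0 = %.2f   lambda = %.4f /d   T = %.2f d\n",
              x$r, x$R0, x$lambda, x$T))
  cat(sprintf("  (Euler-Lotka residual %.2e)\n", x$euler_residual))
  invisible(x)
}

#' Intrinsic rate implied by published (R0, T)
#'
#' The generation-time identity T = ln(R0) / r rearranged, r = ln(R0) / T.
#' Used to check internal consistency of published parameter tables where
#' the raw cohort data are unavailable.
#'
#' @param R0 net reproductive rate (> 0).
#' @param T mean generation time in days (> 0).
#' @return r in per day.
#' @export
#' @examples
#' r_from_R0_T(54.43, 13.68) # ~0.29
r_from_R0_T <- function(R0, T) {
  stopifnot(R0 > 0, T > 0)
  log(R0) / T
}

#' Cohort life-history summaries
#'
#' Means, standard deviations and counts for the standard cohort report:
#' per-stage developmental times (over individuals that completed the
#' stage), preadult duration and adult longevity by sex (over individuals
#' that reached adulthood), longevity over all n0 individuals including
#' preadult deaths, adult pre-oviposition period APOP (first egg age minus
#' emergence age) and total pre-oviposition period TPOP (first egg age)
#' over females that laid at least one egg, oviposition days (days with
#' >= 1 egg) over laying females, and lifetime fecundity over all adult
#' females (zero layers included).
#'
#' @param cohort a [cohort_table()].
#' @return object of class `cohort_summaries`: data.frame with columns
#'   `metric`, `mean`, `sd`, `n`. Metrics with no qualifying individuals
#'   get NA mean/sd and n = 0.
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  ind <- cohort$individuals
  fec <- cohort$fecundity
  pre <- preadult_stages(cohort)

  row_of <- function(metric, x) {
    x <- x[!is.na(x)]
    data.frame(metric = metric,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x)) stats::sd(x) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(pre, function(s) {
    row_of(s, ind[[paste0("dur_", s)]])
  }))

  adult <- ind$fate == "died_adult"
  adult_days <- ind$death_day - ind$emergence_day
  out <- rbind(
    out,
    row_of("preadult", ind$emergence_day[adult]),
    row_of("adult_female", adult_days[adult & ind$sex == "female"]),
    row_of("adult_male", adult_days[adult & ind$sex == "male"]),
    row_of("adult_all", adult_days[adult]),
    row_of("longevity_all", ind$death_day)
  )

  females <- ind$id[adult & ind$sex == "female"]
  total_eggs <- vapply(females, function(id) {
    sum(fec$eggs[fec$id == id])
  }, numeric(1))
  layers <- females[total_eggs > 0]
  first_egg <- vapply(layers, function(id) {
    min(fec$age_day[fec$id == id & fec$eggs > 0])
  }, numeric(1))
  n_days <- vapply(layers, function(id) {
    length(unique(fec$age_day[fec$id == id & fec$eggs > 0]))
  }, numeric(1))
  emergence <- ind$emergence_day[match(layers, ind$id)]

  out <- rbind(
    out,
    row_of("APOP", first_egg - emergence),
    row_of("TPOP", first_egg),
    row_of("oviposition_days", n_days),
    row_of("fecundity", total_eggs)
  )
  rownames(out) <- NULL
  class(out) <- c("cohort_summaries", "data.frame")
  out
}

#' Full life-table analysis of a cohort
#'
#' Convenience wrapper running [compute_age_stage()], [compute_curves()],
#' [solve_r()], [finalize_parameters()] and [summarize_cohort()].
#'
#' @param cohort a [cohort_table()].
#' @param tol Euler-Lotka residual tolerance passed to [solve_r()].
#' @return object of class `life_table`: list with `asm`, `curves`,
#'   `params` (NULL when the cohort laid no eggs) and `summaries`.
#' @export
#' @examples
#' co <- simulate_cohort(preset_from_table("WT"), simulation_config(seed = 1))
#' lt <- life_table(co)
#' lt$params
life_table <- function(cohort, tol = 1e-10) {
  asm <- compute_age_stage(cohort)
  curves <- compute_curves(asm)
  params <- if (compute_R0(curves) > 0) {
    finalize_parameters(curves, solve_r(curves, tol = tol))
  } else {
    NULL
  }
  structure(list(asm = asm, curves = curves, params = params,
                 summaries = summarize_cohort(cohort),
                 strain_label = cohort$strain_label),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> strain ", x$strain_label, "\n", sep = "")
  if (!is.null(x$params)) print(x$params) else
    cat("  no reproduction recorded; r/lambda/T undefined\n")
  s <- x$summaries
  cat(sprintf("  %-18s %8s %8s %4s\n", "metric", "mean", "sd", "n"))
  for (k in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %8.2f %8.2f %4d\n", s$metric[k], s$mean[k],
                s$sd[k], s$n[k]))
  }
  invisible(x)
}

#' Export life-table curves to CSV
#'
#' Writes two tidy CSVs: `<path>_sxj.csv` in long format (age, stage,
#' Sxj) and `<path>_curves.csv` with one row per age (age, lx, fx_female,
#' mx). These are the data behind the standard four-panel life-table
#' figure (age-stage survival, lx, female fx, mx).
#'
#' @param asm an `age_stage_matrix`.
#' @param curves the matching `life_table_curves`.
#' @param path output path prefix (no extension).
#' @return Invisibly, the two file paths.
#' @export
export_curves <- function(asm, curves, path) {
  stopifnot(inherits(asm, "age_stage_matrix"),
            inherits(curves, "life_table_curves"))
  long <- expand.grid(age = asm$ages, stage = asm$stages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$Sxj <- as.vector(asm$S)
  p1 <- paste0(path, "_sxj.csv")
  utils::write.csv(long, p1, row.names = FALSE, quote = FALSE)
  p2 <- paste0(path, "_curves.csv")
  utils::write.csv(
    data.frame(age = curves$ages, lx = curves$lx,
               fx_female = curves$fx_female, mx = curves$mx),
    p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' Four-panel life-table plot
#'
#' Base-graphics rendition of the standard figure: age-stage survival
#' curves Sxj, then lx, female fx and mx against age.
#'
#' @param x a `life_table`.
#' @param ... ignored.
#' @return Invisibly `x`.
#' @export
plot.life_table <- function(x, ...) {
  asm <- x$asm
  cur <- x$curves
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(asm$ages, asm$S, type = "l", lty = 1,
                    xlab = "age (d)", ylab = "Sxj",
                    main = x$strain_label)
  graphics::legend("topright", legend = asm$stages, lty = 1,
                   col = seq_along(asm$stages), cex = 0.7, bty = "n")
  graphics::plot(cur$ages, cur$lx, type = "s", xlab = "age (d)",
                 ylab = "lx", main = "age-specific survival")
  graphics::plot(cur$ages, cur$fx_female, type = "h", xlab = "age (d)",
                 ylab = "fx (eggs/female)", main = "female fecundity")
  graphics::plot(cur$ages, cur$mx, type = "h", xlab = "age (d)",
                 ylab = "mx", main = "population fecundity")
  invisible(x)
}
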