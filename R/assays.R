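#' Trehalose from the trehalase-difference glucose assay
#'
#' The assay measures free glucose in the supernatant before and after
#' overnight trehalase digestion; the increase is glucose liberated from
#' trehalose. One trehalose (342.30 g/mol) hydrolyses to two glucose
#' (180.16 g/mol each), so the trehalose mass is
#' (after - before) x 342.30 / (2 x 180.16), about 0.95 of the glucose
#' difference. A negative difference (assay noise) is clamped to zero
#' with a warning, never returned negative.
#'
#' @param before glucose before trehalase treatment (ug, >= 0).
#' @param after glucose after trehalase treatment (ug, >= 0).
#' @param units `"glucose_equivalent"` (the raw difference) or
#'   `"trehalose_mass"` (stoichiometric conversion).
#' @return nonnegative numeric (vectorized over inputs).
#' @export
#' @examples
#' trehalose_from_glucose(20, 120, "trehalose_mass") # ~95.0 ug
trehalose_from_glucose <- function(before, after,
                                   units = c("glucose_equivalent",
                                             "trehalose_mass")) {
  units <- match.arg(units)
  stopifnot(all(before >= 0), all(after >= 0),
            length(before) == length(after))
  delta <- after - before
  if (any(delta < 0)) {
    warning("glucose after trehalase below pre-treatment level for ",
            sum(delta < 0), " sample(s); clamped to 0 (assay noise)",
            call. = FALSE)
    delta <- pmax(delta, 0)
  }
  if (units == "trehalose_mass") delta * 342.30 / (2 * 180.16) else delta
}

#' Proportion with a Wilson 95% confidence interval
#'
#' @param successes,trials counts, `0 <= successes <= trials`,
#'   `trials > 0`.
#' @return list with `percentage` (0-100, full precision), `lower`,
#'   `upper` (Wilson score 95% bounds, percent), `successes`, `trials`.
#' @export
#' @examples
#' proportion_summary(62, 100)$percentage # 62
#' round(proportion_summary(7, 62)$percentage, 2) # 11.29
proportion_summary <- function(successes, trials) {
  if (trials <= 0) {
    stop("validation error: trials must be > 0", call. = FALSE)
  }
  stopifnot(successes >= 0, successes <= trials)
  # prop.test without continuity correction is the Wilson score interval
  ci <- if (successes %in% c(0, trials)) {
    # prop.test is fine at the boundary too, but suppress its chi-square
    # approximation warning
    suppressWarnings(stats::prop.test(successes, trials,
                                      correct = FALSE)$conf.int)
  } else {
    stats::prop.test(successes, trials, correct = FALSE)$conf.int
  }
  structure(list(percentage = 100 * successes / trials,
                 lower = 100 * ci[1], upper = 100 * ci[2],
                 successes = successes, trials = trials),
            class = "proportion_summary")
}

#' @export
print.proportion_summary <- function(x, ...) {
  cat(sprintf("%.2f%% (%d/%d), Wilson 95%% CI [%.2f%%, %.2f%%]\n",
              x$percentage, x$successes, x$trials, x$lower, x$upper))
  invisible(x)
}

#' Thermal-survival summary across replicates
#'
#' Summarizes alive/total counts from timed heat-stress exposures: per
#' strain x sex x exposure condition, the mean of the per-replicate
#' survival proportions (in percent) and the SE across replicates
#' (SD / sqrt(number of replicates)).
#'
#' @param replicates data.frame with columns `strain`, `sex`,
#'   `exposure_minutes`, `n_alive`, `n_total`.
#' @return data.frame with columns `strain`, `sex`, `exposure_minutes`,
#'   `n_replicates`, `mean_percent`, `se_percent`.
#' @export
#' @examples
#' reps <- data.frame(strain = "WT", sex = "female", exposure_minutes = 30,
#'                    n_alive = c(10, 12, 14, 16), n_total = 20)
#' survival_summary(reps) # 65% +- 6.455
survival_summary <- function(replicates) {
  need <- c("strain", "sex", "exposure_minutes", "n_alive", "n_total")
  miss <- setdiff(need, names(replicates))
  if (length(miss)) {
    stop("schema error: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  with(replicates, stopifnot(all(n_alive >= 0), all(n_alive <= n_total),
                             all(n_total > 0)))
  replicates$pct <- 100 * replicates$n_alive / replicates$n_total
  grp <- interaction(replicates$strain, replicates$sex,
                     replicates$exposure_minutes, drop = TRUE)
  parts <- split(replicates, grp)
  out <- do.call(rbind, lapply(parts, function(g) {
    data.frame(strain = g$strain[1], sex = g$sex[1],
               exposure_minutes = g$exposure_minutes[1],
               n_replicates = nrow(g),
               mean_percent = mean(g$pct),
               se_percent = if (nrow(g) > 1) {
                 stats::sd(g$pct) / sqrt(nrow(g))
               } else {
                 NA_real_
               },
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$strain, out$sex, out$exposure_minutes), ]
  rownames(out) <- NULL
  out
}
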