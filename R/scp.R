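#' Simulate a 1 Hz cooling curve with a freezing exotherm
#'
#' Generates the canonical supercooling trace: a linear decline from
#' `start_temp` down to the supercooling point `scp`, an instantaneous
#' exotherm jump to the freezing point `fp` (latent heat release), a
#' plateau at `fp`, and a resumed linear decline, sampled at 1 Hz with
#' optional Gaussian sensor noise. With `noise_sd = 0` the minimum before
#' the jump is exactly `scp` and the plateau maximum exactly `fp`, so
#' [detect_scp()] inverts the simulation.
#'
#' @param scp supercooling point, deg C.
#' @param fp freezing point, deg C; must exceed `scp`.
#' @param rate cooling rate, deg C per second by default (0.5, as
#'   published for the assay refrigerator; see `rate_unit`).
#' @param noise_sd sensor noise SD, deg C (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @param rate_unit `"per_s"` (as printed in the protocol) or
#'   `"per_min"` (the physically usual magnitude for SCP assays).
#' @param start_temp starting temperature, deg C.
#' @param plateau_s plateau duration at `fp`, seconds.
#' @param post_drop how far below `scp` the final decline runs, deg C.
#' @param pupa_id identifier carried on the curve.
#' @return object of class `cooling_curve`: data.frame with columns `t`
#'   (seconds), `temp` (deg C) and attribute `pupa_id`.
#' @export
simulate_cooling_curve <- function(scp, fp, rate = 0.5, noise_sd = 0,
                                   seed = 1,
                                   rate_unit = c("per_s", "per_min"),
                                   start_temp = 5, plateau_s = 30,
                                   post_drop = 8, pupa_id = "pupa-1") {
  rate_unit <- match.arg(rate_unit)
  if (fp <= scp) {
    stop("parameter error: fp must exceed scp", call. = FALSE)
  }
  step <- if (rate_unit == "per_s") rate else rate / 60
  stopifnot(step > 0, start_temp > scp)

  decline1 <- seq(start_temp, scp, by = -step)
  if (decline1[length(decline1)] > scp) decline1 <- c(decline1, scp)
  plateau <- rep(fp, max(1L, as.integer(plateau_s)))
  end2 <- scp - post_drop
  decline2 <- if (fp - step > end2) seq(fp - step, end2, by = -step) else end2
  temp <- c(decline1, plateau, decline2)

  if (noise_sd > 0) {
    temp <- with_preserved_rng(seed,
                               temp + stats::rnorm(length(temp), 0,
                                                   noise_sd))
  }
  out <- data.frame(t = seq_along(temp) - 1L, temp = temp)
  attr(out, "pupa_id") <- pupa_id
  class(out) <- c("cooling_curve", "data.frame")
  out
}

#' Detect the supercooling point and freezing point in a cooling curve
#'
#' Scans a 1 Hz temperature trace for the exotherm: the first index where
#' the (moving-median smoothed) temperature, after declining, rises by at
#' least `jump_threshold` within the following 3 seconds. The
#' supercooling point is the raw minimum in the `smooth_window` samples up
#' to the reversal (the lowest body temperature before spontaneous
#' freezing); the freezing point is the raw maximum of the post-jump
#' plateau, taken up to the point where the smoothed trace has fallen
#' clearly below the plateau peak again. A curve with no such reversal
#' (e.g. strictly monotone cooling) returns `detected = FALSE` rather
#' than an error.
#'
#' @param curve a `cooling_curve` (or data.frame with `t`, `temp`),
#'   >= 60 samples at strictly increasing 1-s spacing.
#' @param jump_threshold minimum rise (deg C) within 3 s that counts as
#'   the exotherm. Default 0.5: far below the several-degree SCP-to-FP
#'   gap of real exotherms, far above 0.05 deg C sensor noise.
#' @param smooth_window moving-median window in samples (odd; default 3).
#' @return object of class `scp_call`: list with `scp`, `fp`,
#'   `reversal_index` (1-based sample index), `detected`, `pupa_id`.
#' @export
#' @examples
#' cv <- simulate_cooling_curve(scp = -20.9, fp = -7.7)
#' detect_scp(cv)
detect_scp <- function(curve, jump_threshold = 0.5, smooth_window = 3) {
  stopifnot(all(c("t", "temp") %in% names(curve)))
  if (nrow(curve) < 60) {
    stop("validation error: cooling curve needs >= 60 samples",
         call. = FALSE)
  }
  if (any(diff(curve$t) <= 0)) {
    stop("validation error: time must be strictly increasing",
         call. = FALSE)
  }
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
  temp <- curve$temp
  n <- length(temp)
  sm <- as.numeric(stats::runmed(temp, smooth_window))

  no_call <- structure(list(scp = NA_real_, fp = NA_real_,
                            reversal_index = NA_integer_,
                            detected = FALSE,
                            pupa_id = attr(curve, "pupa_id")),
                       class = "scp_call")

  # candidate reversal: last sample of a declining run from which the
  # smoothed trace starts rising and gains >= jump_threshold within 3 s
  rev_i <- NA_integer_
  for (i in 2:(n - 1)) {
    ahead <- sm[seq(i + 1, min(i + 3, n))]
    if (sm[i] <= sm[i - 1] && sm[i + 1] > sm[i] &&
        max(ahead) - sm[i] >= jump_threshold) {
      rev_i <- i
      break
    }
  }
  if (is.na(rev_i)) return(no_call)

  lo <- max(1L, rev_i - smooth_window)
  scp <- min(temp[lo:rev_i])

  # end of plateau: smoothed trace has dropped well below its running
  # post-jump maximum (decline resumed)
  run_max <- sm[rev_i]
  end_i <- n
  for (j in seq(rev_i + 1, n)) {
    run_max <- max(run_max, sm[j])
    if (run_max - sm[j] >= max(1, jump_threshold)) {
      end_i <- j
      break
    }
  }
  fp <- max(temp[rev_i:end_i])
  if (!(fp > scp)) return(no_call)

  structure(list(scp = scp, fp = fp, reversal_index = rev_i,
                 detected = TRUE, pupa_id = attr(curve, "pupa_id")),
            class = "scp_call")
}

#' @export
print.scp_call <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("<scp_call> %s: SCP %.2f degC, FP %.2f degC (reversal at sample %d)\n",
                x$pupa_id %||% "?", x$scp, x$fp, x$reversal_index))
  } else {
    cat("<scp_call> no exotherm detected\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
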