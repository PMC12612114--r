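# Growth and lysis kinetics: sliding-window maximum specific growth rate,
# doubling time, one-step growth curve parameters (latent period, burst
# size), lysis metrics and yield ratios.

#' Maximum specific growth rate by sliding-window log-linear fit
#'
#' Slides a window of width `window_min` across the count series at the
#' data's native sampling; within each window with at least 3 points and all
#' counts >= 1, fits `ln(count) ~ time` by least squares. The specific
#' growth rate SR is the maximum slope over windows; the winning window and
#' its R-squared are reported. Windows containing zero counts are skipped
#' (log undefined) rather than floored.
#'
#' @param series count-series data frame (columns `time_min`, `species`,
#'   `raw_count` and optionally `smoothed_count`), or a plain numeric vector
#'   of counts with `times` supplied.
#' @param species species to analyze when `series` is a data frame.
#' @param window_min window width in minutes (default 20).
#' @param use `"smoothed"` to fit on smoothed counts when available,
#'   `"raw"` to force raw counts.
#' @param times sample times in minutes when `series` is a numeric vector.
#' @return list of class `growth_estimate`: `sr_per_min`, `td_min`,
#'   `window_start_min`, `window_end_min`, `fit_quality` (R-squared).
#' @export
max_specific_growth_rate <- function(series, species = NULL,
                                     window_min = 20, use = c("smoothed",
                                                              "raw"),
                                     times = NULL) {
  use <- match.arg(use)
  if (is.data.frame(series)) {
    if (!is.null(species))
      series <- series[series$species == species, , drop = FALSE]
    series <- series[order(series$time_min), , drop = FALSE]
    t <- series$time_min
    y <- if (use == "smoothed" && "smoothed_count" %in% names(series))
      series$smoothed_count else series$raw_count
  } else {
    y <- as.numeric(series)
    t <- if (is.null(times)) (seq_along(y) - 1) * 5 else times
  }
  if (length(y) < 3) stop("no growth estimate: need >= 3 points",
                          call. = FALSE)
  best <- NULL
  for (i in seq_along(t)) {
    idx <- which(t >= t[i] & t <= t[i] + window_min)
    if (length(idx) < 3) next
    yy <- y[idx]
    if (any(yy < 1)) next
    tt <- t[idx]
    fit <- stats::lm.fit(cbind(1, tt), log(yy))
    slope <- fit$coefficients[2]
    if (is.null(best) || slope > best$sr_per_min) {
      ss_res <- sum(fit$residuals^2)
      ss_tot <- sum((log(yy) - mean(log(yy)))^2)
      r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
      best <- list(sr_per_min = unname(slope),
                   window_start_min = tt[1],
                   window_end_min = tt[length(tt)],
                   fit_quality = max(0, min(1, r2)))
    }
  }
  if (is.null(best))
    stop("no growth estimate: no window with >= 3 nonzero counts",
         call. = FALSE)
  best$td_min <- doubling_time(best$sr_per_min)
  class(best) <- "growth_estimate"
  best
}

#' Doubling time from a specific growth rate
#'
#' `T_D = ln(2) / SR`. A nonpositive rate (lysis or stationary phase) has no
#' doubling time and returns `NA`.
#'
#' @param sr_per_min specific growth rate in 1/min.
#' @return doubling time in minutes, or `NA_real_` when `sr_per_min <= 0`.
#' @examples
#' doubling_time(log(2) / 30) # 30
#' @export
doubling_time <- function(sr_per_min) {
  stopifnot_scalar_num(sr_per_min, "sr_per_min")
  if (sr_per_min <= 0) return(NA_real_)
  log(2) / sr_per_min
}

# Longest initial run of samples within rel_tol of the first sample.
initial_plateau_length <- function(pfu, rel_tol = 0.2) {
  ref <- pfu[1]
  if (ref <= 0) return(1L)
  ok <- abs(pfu - ref) <= rel_tol * ref
  if (!ok[1]) return(1L)
  run <- which(!ok)
  if (length(run) == 0) length(pfu) else run[1] - 1L
}

#' Latent period from a one-step growth curve
#'
#' The baseline is the mean of the initial plateau (the longest initial run
#' of samples within 20% of the first sample). The latent period (time to
#' first burst) is the first sampled time at which the PFU count exceeds
#' `rise_factor` times the baseline.
#'
#' @param times_min,pfu the one-step curve (increasing times; PFU counts or
#'   titers).
#' @param rise_factor rise threshold relative to baseline (default 2).
#' @return latent period in minutes.
#' @export
estimate_latent_period <- function(times_min, pfu, rise_factor = 2.0) {
  if (length(times_min) != length(pfu) || length(pfu) < 3)
    stop("need >= 3 matched samples", call. = FALSE)
  if (is.unsorted(times_min, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  np <- initial_plateau_length(pfu)
  baseline <- mean(pfu[seq_len(np)])
  hit <- which(pfu > rise_factor * baseline)
  hit <- hit[hit > np]
  if (length(hit) == 0)
    stop("no burst detected: curve never rises above threshold",
         call. = FALSE)
  times_min[hit[1]]
}

#' Burst size from a one-step growth curve
#'
#' Ratio of the post-burst plateau to the pre-burst plateau, each detected as
#' the maximal run at the corresponding end of the curve with relative spread
#' below `plateau_tol`. In a one-step assay every infected cell counts as one
#' infective center before lysis and as `burst` plaque-forming units after,
#' so the plateau ratio is the mean burst size.
#'
#' @param times_min,pfu the one-step curve.
#' @param plateau_tol relative spread defining a plateau (default 0.2).
#' @return estimated burst size (phages per lysed cell).
#' @export
estimate_burst_size <- function(times_min, pfu, plateau_tol = 0.2) {
  if (length(times_min) != length(pfu) || length(pfu) < 3)
    stop("need >= 3 matched samples", call. = FALSE)
  np <- initial_plateau_length(pfu, plateau_tol)
  pre <- mean(pfu[seq_len(np)])
  if (pre <= 0)
    stop("cannot estimate burst size: empty pre-burst plateau",
         call. = FALSE)
  if (np == length(pfu)) return(1)   # one flat plateau: no productive burst
  rev_pfu <- rev(pfu)
  nq <- initial_plateau_length(rev_pfu, plateau_tol)
  post <- mean(rev_pfu[seq_len(nq)])
  if (np + nq > length(pfu))
    stop("cannot estimate burst size: no distinct plateaus", call. = FALSE)
  post / pre
}

#' Lysis metrics of a count series
#'
#' Peak count and its time on the smoothed series, plus the time of
#' suppression: the first time after the peak at which the smoothed count
#' falls below `suppression_threshold` (populations held below ~5 cells are
#' considered suppressed).
#'
#' @param series count-series data frame.
#' @param species species to analyze.
#' @param suppression_threshold suppression level in cells (default 5).
#' @return list of class `lysis_metrics`: `peak_count`, `time_to_peak_min`,
#'   `time_to_suppression_min` (`NA` if never suppressed), `final_count`.
#' @export
lysis_metrics <- function(series, species = NULL, suppression_threshold = 5) {
  if (!is.null(species))
    series <- series[series$species == species, , drop = FALSE]
  if (nrow(series) == 0) stop("empty series", call. = FALSE)
  series <- series[order(series$time_min), , drop = FALSE]
  y <- if ("smoothed_count" %in% names(series)) series$smoothed_count
       else series$raw_count
  t <- series$time_min
  ipk <- which.max(y)
  after <- which(y < suppression_threshold & seq_along(y) > ipk)
  structure(list(
    peak_count = y[ipk],
    time_to_peak_min = t[ipk],
    time_to_suppression_min = if (length(after)) t[after[1]] else NA_real_,
    final_count = y[length(y)]),
    class = "lysis_metrics")
}

#' Yield ratio between two species
#'
#' Smoothed count of species A over species B at the sample nearest
#' `at_time_min`.
#'
#' @param series count-series data frame with both species.
#' @param species_a,species_b numerator and denominator species.
#' @param at_time_min evaluation time (default: last sample).
#' @return ratio, or `NA_real_` when the denominator is 0.
#' @export
yield_ratio <- function(series, species_a = "PA", species_b = "SA",
                        at_time_min = NULL) {
  pick <- function(sp) {
    s <- series[series$species == sp, , drop = FALSE]
    s <- s[order(s$time_min), , drop = FALSE]
    if (nrow(s) == 0) stop("species absent from series: ", sp, call. = FALSE)
    tt <- if (is.null(at_time_min)) s$time_min[nrow(s)] else at_time_min
    i <- which.min(abs(s$time_min - tt))
    y <- if ("smoothed_count" %in% names(s)) s$smoothed_count
         else s$raw_count
    y[i]
  }
  a <- pick(species_a); b <- pick(species_b)
  if (b == 0) return(NA_real_)
  a / b
}
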