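# Processing of quantified punctum time courses: synchronization, spline
# assisted alignment, irregularity filtering, trimming, bleaching
# regularization, population summaries and peak-train extraction.

split_traces <- function(traces) {
  stopifnot(is.data.frame(traces),
            all(c("repeat_id", "time_s", "intensity_au") %in% names(traces)))
  split(traces, factor(traces$repeat_id, levels = unique(traces$repeat_id)))
}

bind_traces <- function(lst) do.call(rbind, c(lst, list(make.row.names = FALSE)))

#' Synchronize traces on their maximum-intensity peak
#'
#' Shifts each repeat's time axis so that its global maximum (earliest
#' sample in case of ties) sits at 0 s, the reference used before fitting
#' pulse models to asynchronously triggered autophagy events.
#'
#' @param traces Long data.frame with columns `repeat_id`, `time_s`,
#'   `intensity_au` (a `condition` column is carried through if present).
#' @param refine Use sub-frame apex localization (parabola through the three
#'   samples around the maximum) and re-grid the shifted trace by linear
#'   interpolation. Grid-level synchronization smears the population mean by
#'   up to half a frame; refinement removes most of that blur before
#'   averaging and fitting.
#' @return The synchronized long data.frame.
#' @export
synchronize_on_peak <- function(traces, refine = FALSE) {
  out <- lapply(split_traces(traces), function(tr) {
    if (diff(range(tr$intensity_au)) == 0) {
      stop(sprintf("no peak: trace '%s' is flat", tr$repeat_id[1]))
    }
    i <- which.max(tr$intensity_au)
    t_peak <- tr$time_s[i]
    if (refine && i > 1 && i < nrow(tr)) {
      y1 <- tr$intensity_au[i - 1]; y2 <- tr$intensity_au[i]
      y3 <- tr$intensity_au[i + 1]
      denom <- y1 - 2 * y2 + y3
      if (denom < 0) {
        frac <- 0.5 * (y1 - y3) / denom
        if (abs(frac) <= 1) {
          t_peak <- t_peak + frac * (tr$time_s[i + 1] - tr$time_s[i - 1]) / 2
        }
      }
    }
    rel <- tr$time_s - t_peak
    if (refine) {
      dt <- stats::median(diff(tr$time_s))
      grid <- seq(ceiling(min(rel) / dt) * dt, floor(max(rel) / dt) * dt,
                  by = dt)
      vals <- stats::approx(rel, tr$intensity_au, xout = grid)$y
      tr <- tr[rep(1L, length(grid)), , drop = FALSE]
      tr$time_s <- grid
      tr$intensity_au <- vals
    } else {
      tr$time_s <- rel
    }
    tr
  })
  bind_traces(out)
}

# ---- peak detection ---------------------------------------------------------

# indices of strict local maxima, plateau-aware (first index of a plateau)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  keep <- !duplicated(cumsum(c(TRUE, diff(x) != 0)))  # first index per run
  xi <- x[keep]
  idx <- which(keep)
  m <- length(xi)
  if (m < 3) return(integer(0))
  cand <- which(xi[2:(m - 1)] > xi[1:(m - 2)] & xi[2:(m - 1)] > xi[3:m]) + 1L
  idx[cand]
}

# topographic prominence of each peak index in x
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(i) {
    v <- x[i]
    left <- if (i > 1) x[1:(i - 1)] else numeric(0)
    right <- if (i < length(x)) x[(i + 1):length(x)] else numeric(0)
    base_side <- function(side, rev_side = FALSE) {
      if (length(side) == 0) return(min(x))
      if (rev_side) side <- rev(side)          # walk outward from the peak
      higher <- which(side > v)
      if (length(higher) > 0) min(side[1:higher[1]]) else min(side)
    }
    lb <- base_side(left, rev_side = TRUE)
    rb <- base_side(right)
    v - max(lb, rb)
  }, numeric(1))
}

#' Extract the alternating peak/trough train of an oscillatory trace
#'
#' Detects upper aggregation peaks by topographic prominence, places one
#' trough at the minimum between successive retained peaks, and reports the
#' successive upper and lower delays plus rise-time statistics (trough to
#' following peak, with the first rise measured from the trace start). The
#' rise-time mean and SD are the empirical inputs for the per-cycle
#' time-to-peak distribution of the mitophagy model.
#'
#' @param trace data.frame with `time_s` and `intensity_au`.
#' @param min_prominence Minimum peak prominence; default 10% of the trace
#'   range.
#' @param min_separation_s Minimum time between retained peaks (s);
#'   default 20 s (two imaging frames).
#' @return An object of class `peak_train`: list with `upper_peaks`,
#'   `troughs` (data.frames `time_s`, `value`), `upper_delays`,
#'   `lower_delays`, `rise_times`, `t_mean`, `t_sd`.
#' @export
detect_peaks <- function(trace, min_prominence = NULL, min_separation_s = 20) {
  x <- trace$intensity_au
  tt <- trace$time_s
  rng <- diff(range(x))
  if (is.null(min_prominence)) min_prominence <- 0.1 * rng
  cand <- local_maxima(x)
  empty <- list(
    upper_peaks = data.frame(time_s = numeric(0), value = numeric(0)),
    troughs = data.frame(time_s = numeric(0), value = numeric(0)),
    upper_delays = numeric(0), lower_delays = numeric(0),
    rise_times = numeric(0), t_mean = NA_real_, t_sd = NA_real_
  )
  if (length(cand) == 0 || rng == 0) return(structure(empty, class = "peak_train"))
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) return(structure(empty, class = "peak_train"))
  # greedy by height, enforce the minimum separation
  kept <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (all(abs(tt[i] - tt[kept]) >= min_separation_s)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  # sub-frame apex localization: parabola through the three samples around
  # each retained peak (peak positions are otherwise quantized to the frame
  # interval, which blurs the inter-peak delay statistics)
  peak_t <- tt[kept]
  peak_v <- x[kept]
  for (j in seq_along(kept)) {
    i <- kept[j]
    if (i > 1 && i < length(x)) {
      y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
      denom <- y1 - 2 * y2 + y3
      if (denom < 0) {
        frac <- 0.5 * (y1 - y3) / denom
        if (abs(frac) <= 1) {
          h <- (tt[i + 1] - tt[i - 1]) / 2
          peak_t[j] <- tt[i] + frac * h
          peak_v[j] <- y2 - 0.25 * (y1 - y3) * frac
        }
      }
    }
  }
  troughs <- integer(0)
  if (length(kept) >= 2) {
    troughs <- vapply(seq_len(length(kept) - 1L), function(j) {
      seg <- kept[j]:kept[j + 1L]
      seg[which.min(x[seg])]
    }, integer(1))
  }
  rise <- c(
    peak_t[1] - tt[1],
    if (length(kept) >= 2) peak_t[-1] - tt[troughs]
  )
  rise <- rise[rise > 0]
  structure(list(
    upper_peaks = data.frame(time_s = peak_t, value = peak_v),
    troughs = data.frame(time_s = tt[troughs], value = x[troughs]),
    upper_delays = diff(peak_t),
    lower_delays = diff(tt[troughs]),
    rise_times = rise,
    t_mean = if (length(rise)) mean(rise) else NA_real_,
    t_sd = if (length(rise) > 1) stats::sd(rise) else NA_real_
  ), class = "peak_train")
}

#' Remove the slow fluorescence decline from a trace
#'
#' Fits an exponential baseline to the trough envelope (local minima plus the
#' trace endpoints) and divides it out, normalized to 1 at the first sample.
#' A rising envelope is left untouched (no decline to remove). This
#' compensates the gradual photobleaching-like signal loss of long
#' fluorescence acquisitions.
#'
#' @param trace data.frame with `time_s` and `intensity_au` (length >= 5).
#' @return The regularized trace; on fit failure the input is returned
#'   unchanged with a warning.
#' @export
regularize_decline <- function(trace) {
  stopifnot(nrow(trace) >= 5)
  x <- trace$intensity_au
  tt <- trace$time_s
  mins <- local_maxima(-x)
  env_idx <- sort(unique(c(1L, mins, length(x))))
  if (length(env_idx) < 3 || any(x[env_idx] <= 0)) {
    warning("trough-envelope fit failed; returning trace unchanged")
    return(trace)
  }
  fit <- try(stats::lm(log(x[env_idx]) ~ tt[env_idx]), silent = TRUE)
  if (inherits(fit, "try-error")) {
    warning("trough-envelope fit failed; returning trace unchanged")
    return(trace)
  }
  slope <- stats::coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) return(trace)
  trace$intensity_au <- x / exp(slope * (tt - tt[1]))
  trace
}

#' Per-time-point population summary of aligned traces
#'
#' @param traces Long data.frame of trimmed, aligned traces.
#' @return data.frame (class `population_summary`) with `time_s`, `mean`,
#'   `sd`, `ci95_halfwidth` (t-distribution CI of the mean) and
#'   `n_per_timepoint`.
#' @export
summarize_population <- function(traces) {
  by_t <- split(traces$intensity_au, traces$time_s)
  n <- vapply(by_t, length, integer(1))
  if (any(n < 2)) {
    stop("fewer than 2 repeats at some time points; trim the traces first")
  }
  out <- data.frame(
    time_s = as.numeric(names(by_t)),
    mean = vapply(by_t, mean, numeric(1)),
    sd = vapply(by_t, stats::sd, numeric(1)),
    n_per_timepoint = n
  )
  out$ci95_halfwidth <- stats::qt(0.975, out$n_per_timepoint - 1) *
    out$sd / sqrt(out$n_per_timepoint)
  out <- out[order(out$time_s), ]
  rownames(out) <- NULL
  class(out) <- c("population_summary", "data.frame")
  out
}

# mean over traces at each common time point, NA-tolerant
population_reference <- function(lst) {
  all_t <- sort(unique(unlist(lapply(lst, `[[`, "time_s"))))
  vals <- sapply(lst, function(tr) tr$intensity_au[match(all_t, tr$time_s)])
  list(time_s = all_t, mean = rowMeans(as.matrix(vals), na.rm = TRUE))
}

best_shift <- function(tr, ref, dt, max_shift) {
  shifts <- seq(-max_shift, max_shift)
  score <- vapply(shifts, function(s) {
    shifted_t <- tr$time_s + s * dt
    idx <- match(shifted_t, ref$time_s)
    ok <- !is.na(idx)
    if (sum(ok) < 5) return(-Inf)
    a <- tr$intensity_au[ok]
    b <- ref$mean[idx[ok]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))
  shifts[which.max(score)]
}

#' Prepare mitophagy time courses for population analysis
#'
#' Fixed pipeline: spline-smooth each trace, iteratively align the splined
#' traces to the population average by integer-frame cross-correlation
#' shifts, restore the original (unsplined) values at the aligned times,
#' drop irregular traces, and trim the time window so that every retained
#' time point has at least `min_repeats` repeats. A trace is irregular when
#' it has no detectable peak, when the coefficient of variation of its
#' inter-peak delays exceeds `irregularity_cfg$max_delay_cv`, or when more
#' than `irregularity_cfg$max_missing_frac` of its frames are missing.
#'
#' @param traces Long data.frame (`repeat_id`, `time_s`, `intensity_au`).
#' @param spline_df Smoothing-spline degrees of freedom; default
#'   `max(4, n_frames / 5)` per trace.
#' @param irregularity_cfg List with `max_delay_cv` (default 1.5) and
#'   `max_missing_frac` (default 0.2).
#' @param min_repeats Minimum repeats per retained time point (default 3).
#' @param max_shift_frames Alignment search radius in frames (default 20).
#' @return The processed long data.frame, with a `provenance` attribute
#'   recording shifts, dropped traces (id + reason) and the trimmed window.
#' @export
mitophagy_prepare <- function(traces, spline_df = NULL,
                              irregularity_cfg = list(max_delay_cv = 1.5,
                                                      max_missing_frac = 0.2),
                              min_repeats = 3, max_shift_frames = 20) {
  lst <- split_traces(traces)
  if (length(lst) < min_repeats) stop("fewer traces than min_repeats")
  dt <- stats::median(unlist(lapply(lst, function(tr) diff(tr$time_s))))
  cfg <- utils::modifyList(list(max_delay_cv = 1.5, max_missing_frac = 0.2),
                           as.list(irregularity_cfg))

  splined <- lapply(lst, function(tr) {
    n <- nrow(tr)
    df_i <- if (is.null(spline_df)) max(4, round(n / 5)) else spline_df
    fit <- stats::smooth.spline(tr$time_s, tr$intensity_au,
                                df = min(df_i, n - 1))
    tr$intensity_au <- stats::predict(fit, tr$time_s)$y
    tr
  })

  shifts <- rep(0L, length(lst))
  for (iter in 1:10) {
    shifted <- Map(function(tr, s) { tr$time_s <- tr$time_s + s * dt; tr },
                   splined, shifts)
    ref <- population_reference(shifted)
    new_shifts <- vapply(seq_along(splined), function(i) {
      shifts[i] + best_shift(shifted[[i]], ref, dt, max_shift_frames)
    }, numeric(1))
    if (all(new_shifts == shifts)) break
    shifts <- new_shifts
  }

  aligned <- Map(function(tr, s) { tr$time_s <- tr$time_s + s * dt; tr },
                 lst, shifts)
  aligned_spl <- Map(function(tr, s) { tr$time_s <- tr$time_s + s * dt; tr },
                     splined, shifts)

  dropped <- list()
  keep <- logical(length(aligned))
  for (i in seq_along(aligned)) {
    tr <- aligned[[i]]
    spl <- aligned_spl[[i]]
    id <- tr$repeat_id[1]
    full_grid <- seq(min(tr$time_s), max(tr$time_s), by = dt)
    missing_frac <- 1 - nrow(tr) / length(full_grid)
    train <- detect_peaks(spl)
    n_peaks <- nrow(train$upper_peaks)
    delay_cv <- if (length(train$upper_delays) >= 2) {
      stats::sd(train$upper_delays) / mean(train$upper_delays)
    } else 0
    reason <- if (n_peaks == 0) {
      "no detectable peak"
    } else if (delay_cv > cfg$max_delay_cv) {
      sprintf("inter-peak delay CV %.2f > %.2f", delay_cv, cfg$max_delay_cv)
    } else if (missing_frac > cfg$max_missing_frac) {
      sprintf("%.0f%% of frames missing", 100 * missing_frac)
    } else {
      NA_character_
    }
    keep[i] <- is.na(reason)
    if (!keep[i]) dropped[[id]] <- reason
  }
  surviving <- aligned[keep]
  if (length(surviving) < min_repeats) {
    stop("fewer than min_repeats traces survive the irregularity filter")
  }

  counts <- table(unlist(lapply(surviving, `[[`, "time_s")))
  good_t <- as.numeric(names(counts))[counts >= min_repeats]
  window <- range(good_t)
  trimmed <- lapply(surviving, function(tr) {
    tr[tr$time_s >= window[1] & tr$time_s <= window[2] &
         tr$time_s %in% good_t, , drop = FALSE]
  })
  out <- bind_traces(trimmed)
  attr(out, "provenance") <- list(
    steps = c("spline", "align", "restore", "filter", "trim"),
    frame_dt = dt,
    shifts = stats::setNames(shifts * dt, names(lst)),
    dropped = dropped,
    window = window
  )
  out
}

#' Correlate per-event peak counts with mitochondrial diameters
#'
#' @param peak_counts Integer vector, one count per mitophagy event.
#' @param diameters Diameters in micrometres, same length.
#' @param conf_level Confidence level of the regression band.
#' @return List with `r`, `p_value`, `fit` (the `lm`), and `band`
#'   (data.frame `diameter`, `fit`, `lwr`, `upr`).
#' @export
correlate_counts_diameters <- function(peak_counts, diameters,
                                       conf_level = 0.95) {
  stopifnot(length(peak_counts) == length(diameters), length(diameters) >= 3)
  if (stats::sd(peak_counts) == 0 || stats::sd(diameters) == 0) {
    stop("correlation undefined: zero variance in counts or diameters")
  }
  ct <- stats::cor.test(diameters, peak_counts, method = "pearson")
  fit <- stats::lm(peak_counts ~ diameters)
  grid <- data.frame(diameters = seq(min(diameters), max(diameters),
                                     length.out = 50))
  pr <- stats::predict(fit, grid, interval = "confidence", level = conf_level)
  list(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    fit = fit,
    band = data.frame(diameter = grid$diameters, fit = pr[, "fit"],
                      lwr = pr[, "lwr"], upr = pr[, "upr"])
  )
}

#' Summarize per-event mitochondrial diameter measurements
#'
#' Each event's diameter is the arithmetic mean of its (>= 8) measurements;
#' the population mean and SD define the diameter distribution used by the
#' mitophagy model, with a Shapiro-Wilk normality check.
#'
#' @param measurements data.frame with `event_id` and `measurement_um`.
#' @param min_measurements Warn when an event has fewer measurements.
#' @return Object of class `diameter_stats`: list with `per_event_means`,
#'   `mean`, `sd`, `shapiro_p`, `n_events`.
#' @export
diameter_stats <- function(measurements, min_measurements = 8) {
  stopifnot(all(c("event_id", "measurement_um") %in% names(measurements)),
            all(measurements$measurement_um > 0))
  by_event <- split(measurements$measurement_um, measurements$event_id)
  short <- names(by_event)[vapply(by_event, length, integer(1)) < min_measurements]
  if (length(short) > 0) {
    warning(sprintf("events with fewer than %d measurements: %s",
                    min_measurements, paste(short, collapse = ", ")))
  }
  means <- vapply(by_event, mean, numeric(1))
  structure(list(
    per_event_means = means,
    mean = mean(means),
    sd = stats::sd(means),
    shapiro_p = if (length(means) >= 3) stats::shapiro.test(means)$p.value else NA_real_,
    n_events = length(means)
  ), class = "diameter_stats")
}

#' Extract and synchronize the first aggregation peak of each trace
#'
#' Cuts each trace at the first trough following its first detected peak and
#' synchronizes the cut segments on the peak, producing the reduced data set
#' used for stage-1 calibration of the mitophagy ATG13 rate constants.
#'
#' @param traces Long data.frame of (regularized) mitophagy traces.
#' @param prominence_frac Per-trace prominence threshold as a fraction of
#'   that trace's intensity range (default 0.2: strict enough to ignore
#'   baseline noise wiggles, loose enough to keep weak first cycles).
#' @param ... Passed to [detect_peaks()].
#' @return Synchronized long data.frame of first-peak segments.
#' @export
extract_first_peak <- function(traces, prominence_frac = 0.2, ...) {
  lst <- split_traces(traces)
  cut <- lapply(lst, function(tr) {
    train <- detect_peaks(tr,
                          min_prominence = prominence_frac *
                            diff(range(tr$intensity_au)), ...)
    if (nrow(train$upper_peaks) == 0) {
      stop(sprintf("no peak in trace '%s'", tr$repeat_id[1]))
    }
    end_t <- if (nrow(train$troughs) >= 1) {
      train$troughs$time_s[1]
    } else {
      max(tr$time_s)
    }
    tr[tr$time_s <= end_t, , drop = FALSE]
  })
  synchronize_on_peak(bind_traces(cut))
}
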