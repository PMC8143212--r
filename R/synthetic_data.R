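# Synthetic fixture generation: populations with the statistical structure
# the analysis assumes, bundled with their generating ground truth.

#' Noise configuration for synthetic traces
#'
#' Multiplicative log-normal noise (fluorescence-like, mean 1) plus a shared
#' exponential photobleaching-style decline.
#'
#' @param sd_frac Multiplicative noise standard deviation as a fraction of
#'   the signal (default 0.05).
#' @param bleach_tau Bleaching time constant in seconds (default 2000,
#'   about a 35% decline over a 900 s acquisition); `Inf` disables the
#'   decline.
#' @return List with `sd_frac`, `bleach_tau`.
#' @export
noise_config <- function(sd_frac = 0.05, bleach_tau = 2000) {
  stopifnot(sd_frac >= 0, bleach_tau > 0)
  list(sd_frac = sd_frac, bleach_tau = bleach_tau)
}

apply_noise <- function(intensity, times, noise_cfg) {
  out <- intensity * exp(-(times - times[1]) / noise_cfg$bleach_tau)
  if (noise_cfg$sd_frac > 0) {
    sdlog <- sqrt(log1p(noise_cfg$sd_frac^2))
    out <- out * stats::rlnorm(length(out), -sdlog^2 / 2, sdlog)
  }
  out
}

default_peak_time_dist <- function(condition) {
  if (condition == "starvation") {
    list(type = "normal", mean = 300, sd = 60)
  } else {
    list(type = "lognormal", meanlog = log(200), sdlog = 0.35)
  }
}

#' Generate a population of nonselective single-pulse traces
#'
#' Each repeat is simulated from the event-based pulse model with an
#' independently sampled event time, then degraded by multiplicative noise
#' and an exponential bleaching decline. Starvation repeats draw peak times
#' from a normal distribution; the wortmannin condition draws log-normal
#' peak times and is simulated with the wortmannin factor active
#' (reduced punctum intensity).
#'
#' @param n Number of repeats.
#' @param condition `"starvation"` or `"starvation+wortmannin"`.
#' @param peak_time_dist Peak-time distribution (see [sample_peak_times()]);
#'   defaults to Normal(300, 60) s for starvation and
#'   LogNormal(log 200, 0.35) for wortmannin.
#' @param params Generating [nonselective_params()].
#' @param noise_cfg A [noise_config()].
#' @param seed Integer seed.
#' @param variant Generating [model_variant()] (default 3, event-based,
#'   wortmannin on both reactions).
#' @param horizon,dt Simulation grid (s).
#' @return Object of class `ground_truth_bundle`: list with `traces` (long
#'   data.frame), `generating_params`, `variant`, `condition`,
#'   `true_peak_times`, `noise_cfg`, `seed`.
#' @export
gen_nonselective_population <- function(n,
                                        condition = c("starvation", "starvation+wortmannin"),
                                        peak_time_dist = NULL,
                                        params = default_nonselective_params(),
                                        noise_cfg = noise_config(),
                                        seed = 1L,
                                        variant = model_variant(3),
                                        horizon = 900, dt = 10) {
  stopifnot(n >= 1)
  condition <- match.arg(condition)
  if (is.null(peak_time_dist)) peak_time_dist <- default_peak_time_dist(condition)
  wortmannin <- condition == "starvation+wortmannin"
  set.seed(seed)
  t_draws <- sample_peak_times(n, peak_time_dist)
  horizon <- max(horizon, max(t_draws) + 2 * dt)
  times <- seq(0, horizon, by = dt)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    p_i <- params
    p_i$t <- t_draws[i]
    A <- nonselective_solution(times, p_i, variant, wortmannin)
    traces[[i]] <- data.frame(
      repeat_id = sprintf("%s_%02d", if (wortmannin) "wrt" else "stv", i),
      condition = condition,
      time_s = times,
      intensity_au = apply_noise(A, times, noise_cfg),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    traces = bind_traces(traces),
    generating_params = params,
    variant = variant,
    condition = condition,
    true_peak_times = as.numeric(t_draws),
    noise_cfg = noise_cfg,
    seed = seed
  ), class = "ground_truth_bundle")
}

# an "irregular" trace: pulse train with erratic inter-peak gaps and heavy
# random frame dropout, exercising the irregularity filter
irregular_trace <- function(id, horizon, dt, baseline, noise_cfg) {
  times <- seq(0, horizon, by = dt)
  gaps <- sample(c(30, 30, 40, 700, 600), 4, replace = TRUE)
  centers <- cumsum(c(60, gaps))
  centers <- centers[centers < horizon]
  x <- rep(baseline, length(times))
  for (ct in centers) x <- x + 2 * baseline * exp(-((times - ct) / 15)^2)
  x <- apply_noise(x, times, noise_cfg)
  keep <- sort(sample(seq_along(times), size = floor(0.65 * length(times))))
  data.frame(
    repeat_id = id, condition = "ivermectin",
    time_s = times[keep], intensity_au = x[keep],
    stringsAsFactors = FALSE
  )
}

#' Generate a population of mitophagy oscillation traces
#'
#' Wraps [simulate_mitophagy_population()], degrades the observable ATG13
#' traces with multiplicative noise and a bleaching decline, and records the
#' generating truth (peak counts, peak times, delays, diameters). Optionally
#' injects irregular traces (erratic inter-peak gaps plus heavy frame
#' dropout) to exercise the filtering pipeline.
#'
#' @param n Total number of traces, including injected irregular ones.
#' @param params Generating [mitophagy_params()].
#' @param noise_cfg A [noise_config()].
#' @param seed Integer seed.
#' @param n_irregular Number of injected irregular traces (default 0).
#' @param dt Frame interval (s).
#' @param horizon Common output horizon (s, default 910: the analysis
#'   window; events still running are truncated, finished ones padded at
#'   baseline).
#' @return Object of class `ground_truth_bundle`: list with `traces`,
#'   `generating_params`, `sims` (the clean `mitophagy_sim` objects),
#'   `true_peak_counts`, `true_peak_times`, `true_delays`,
#'   `true_diameters`, `irregular_ids`, `noise_cfg`, `seed`.
#' @export
gen_mitophagy_population <- function(n, params = default_mitophagy_params(),
                                     noise_cfg = noise_config(), seed = 1L,
                                     n_irregular = 0, dt = 10, horizon = 910) {
  stopifnot(n >= 1, n_irregular >= 0, n_irregular < n)
  n_regular <- n - n_irregular
  sims <- simulate_mitophagy_population(max(n_regular, 2), params, seed = seed,
                                        dt = dt)
  sims <- sims[seq_len(n_regular)]
  common_horizon <- horizon
  traces <- vector("list", n)
  for (i in seq_len(n_regular)) {
    tr <- sims[[i]]$trace
    full <- data.frame(time_s = seq(0, common_horizon, by = dt))
    full$intensity_au <- tr$intensity_au[match(full$time_s, tr$time_s)]
    full$intensity_au[is.na(full$intensity_au)] <- params$atg13_seed
    traces[[i]] <- data.frame(
      repeat_id = sprintf("mito_%02d", i), condition = "ivermectin",
      time_s = full$time_s,
      intensity_au = apply_noise(full$intensity_au, full$time_s, noise_cfg),
      stringsAsFactors = FALSE
    )
  }
  irregular_ids <- character(0)
  if (n_irregular > 0) {
    for (j in seq_len(n_irregular)) {
      id <- sprintf("irregular_%02d", j)
      irregular_ids <- c(irregular_ids, id)
      traces[[n_regular + j]] <- irregular_trace(id, common_horizon, dt,
                                                 params$atg13_seed, noise_cfg)
    }
  }
  structure(list(
    traces = bind_traces(traces),
    generating_params = params,
    sims = sims,
    true_peak_counts = vapply(sims, function(s) length(s$peak_times), integer(1)),
    true_peak_times = lapply(sims, `[[`, "peak_times"),
    true_delays = lapply(sims, `[[`, "peak_delay_obs"),
    true_diameters = vapply(sims, `[[`, numeric(1), "mt_diam"),
    irregular_ids = irregular_ids,
    noise_cfg = noise_cfg,
    seed = seed
  ), class = "ground_truth_bundle")
}

#' Generate a mitochondrial diameter measurement table
#'
#' Per-event true diameters are drawn from a truncated normal; each event
#' receives `per_event_measurements` jittered measurements, matching the
#' diameters CSV schema (`event_id`, `measurement_um`).
#'
#' @param n Number of events.
#' @param mean_um,sd_um Diameter distribution (micrometres).
#' @param per_event_measurements Measurements per event (default 8).
#' @param measurement_sd Measurement jitter SD (micrometres).
#' @param seed Integer seed.
#' @return data.frame with `event_id`, `measurement_um`; the per-event true
#'   diameters are attached as attribute `true_diameters`.
#' @export
gen_diameters <- function(n, mean_um = 0.9, sd_um = 0.25,
                          per_event_measurements = 8, measurement_sd = 0.05,
                          seed = 1L) {
  stopifnot(n >= 1, mean_um > 0, sd_um >= 0, measurement_sd >= 0,
            per_event_measurements >= 1)
  set.seed(seed)
  truth <- truncated_normal(n, mean_um, sd_um)
  rows <- lapply(seq_len(n), function(i) {
    meas <- truth[i] + stats::rnorm(per_event_measurements, 0, measurement_sd)
    while (any(meas <= 0)) {
      bad <- meas <= 0
      meas[bad] <- truth[i] + stats::rnorm(sum(bad), 0, measurement_sd)
    }
    data.frame(event_id = sprintf("event_%02d", i), measurement_um = meas,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "true_diameters") <- truth
  out
}

#' Read / write the standard trace CSV schema
#'
#' Columns: `repeat_id`, `condition`, `time_s`, `intensity_au`.
#'
#' @param traces Long trace data.frame.
#' @param path CSV path.
#' @return `read_traces_csv` returns the data.frame; `write_traces_csv`
#'   returns `path` invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(all(c("repeat_id", "condition", "time_s", "intensity_au") %in%
                  names(traces)))
  utils::write.csv(traces[, c("repeat_id", "condition", "time_s", "intensity_au")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("repeat_id", "condition", "time_s", "intensity_au")
  if (nrow(df) == 0 || !all(need %in% names(df))) {
    stop("malformed trace CSV: need non-empty columns ",
         paste(need, collapse = ", "))
  }
  df
}
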