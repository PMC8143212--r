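#' Simulate one nonselective ATG13 pulse
#'
#' Integrates the selected model variant from the aggregation seed and
#' returns the trajectory on a regular grid (default 10 s, the imaging
#' cadence). Event-based variants accumulate on `[0, t)` and remove on
#' `[t, Inf)`; eventless variants run both reactions simultaneously.
#' The one-dimensional phase dynamics are evaluated from their exact
#' analytic solutions.
#'
#' @param params A [nonselective_params()] object.
#' @param variant A [model_variant()].
#' @param wortmannin Logical; apply the `kwrtm` down-regulation to the
#'   variant's targeted reaction(s).
#' @param horizon Simulation end time (s); must exceed `params$t` for
#'   event-based variants.
#' @param dt Output grid step (s).
#' @param condition,repeat_id Metadata copied into the returned trace.
#' @return A data.frame with columns `repeat_id`, `condition`, `time_s`,
#'   `intensity_au`.
#' @export
#' @examples
#' tc <- simulate_nonselective(default_nonselective_params(), model_variant(3))
#' tc$time_s[which.max(tc$intensity_au)]  # pulse peaks at the event time
simulate_nonselective <- function(params, variant, wortmannin = FALSE,
                                  horizon = 900, dt = 10,
                                  condition = if (wortmannin) "starvation+wortmannin" else "starvation",
                                  repeat_id = "sim_1") {
  stopifnot(dt > 0, horizon > 0)
  if (variant$event_based && (is.na(params$t) || horizon <= params$t)) {
    stop("horizon must exceed the event time t for event-based variants")
  }
  times <- seq(0, horizon, by = dt)
  A <- nonselective_solution(times, params, variant, wortmannin)
  if (any(!is.finite(A))) {
    bad <- times[which(!is.finite(A))[1]]
    stop(sprintf(
      "integration produced non-finite ATG13 at t = %g s (finite-time blow-up; check m and kprodATG13)",
      bad
    ))
  }
  data.frame(
    repeat_id = repeat_id, condition = condition,
    time_s = times, intensity_au = A,
    stringsAsFactors = FALSE
  )
}

#' Sample peak times from a normal or log-normal distribution
#'
#' Normal draws are truncated at zero by resampling; the number of rejected
#' draws is recorded in the `n_resampled` attribute.
#'
#' @param n Number of draws.
#' @param dist A list, either `list(type = "normal", mean = , sd = )` or
#'   `list(type = "lognormal", meanlog = , sdlog = )`.
#' @return Numeric vector of length `n` with attribute `n_resampled`.
#' @export
sample_peak_times <- function(n, dist) {
  stopifnot(n >= 1, is.list(dist), !is.null(dist$type))
  if (dist$type == "normal") {
    stopifnot(is.finite(dist$mean), dist$sd >= 0)
    draws <- stats::rnorm(n, dist$mean, dist$sd)
    resampled <- 0L
    while (any(draws <= 0)) {
      idx <- which(draws <= 0)
      resampled <- resampled + length(idx)
      draws[idx] <- stats::rnorm(length(idx), dist$mean, dist$sd)
    }
  } else if (dist$type == "lognormal") {
    stopifnot(is.finite(dist$meanlog), dist$sdlog >= 0)
    draws <- stats::rlnorm(n, dist$meanlog, dist$sdlog)
    resampled <- 0L
  } else {
    stop("dist$type must be 'normal' or 'lognormal'")
  }
  attr(draws, "n_resampled") <- resampled
  draws
}

#' Simulate a population kymograph of nonselective pulses
#'
#' Each repeat is simulated with an independently sampled event time `t`,
#' row-normalized to `[0, 1]`, and rows are sorted by decreasing peak time
#' (ties keep repeat order), the layout used for punctum kymographs.
#'
#' @param n Number of simulated repeats.
#' @param peak_time_dist Distribution of the event time, see
#'   [sample_peak_times()].
#' @param params,variant,wortmannin Passed to [simulate_nonselective()].
#' @param seed Integer seed fixing all draws.
#' @param horizon,dt Simulation grid (s).
#' @return An object of class `kymograph`: list with `matrix`
#'   (n x n_timepoints in `[0,1]`), `times`, `row_order`, `peak_times`
#'   (sampled event times, in row order of `matrix`).
#' @export
simulate_kymograph <- function(n, peak_time_dist, params,
                               variant = model_variant(3), wortmannin = FALSE,
                               seed = 1L, horizon = 900, dt = 10) {
  stopifnot(n >= 1)
  set.seed(seed)
  t_draws <- sample_peak_times(n, peak_time_dist)
  if (attr(t_draws, "n_resampled") > 0) {
    message(sprintf("resampled %d non-positive peak-time draws", attr(t_draws, "n_resampled")))
  }
  horizon <- max(horizon, max(t_draws) + dt)
  times <- seq(0, horizon, by = dt)
  mat <- matrix(0, nrow = n, ncol = length(times))
  ids <- sprintf("sim_%02d", seq_len(n))
  obs_peak <- numeric(n)
  for (i in seq_len(n)) {
    p_i <- params
    p_i$t <- t_draws[i]
    A <- nonselective_solution(times, p_i, variant, wortmannin)
    rng <- range(A)
    mat[i, ] <- if (diff(rng) > 0) (A - rng[1]) / diff(rng) else 0
    obs_peak[i] <- times[which.max(A)]
  }
  ord <- order(-obs_peak, seq_len(n))
  structure(
    list(
      matrix = mat[ord, , drop = FALSE],
      times = times,
      row_order = ids[ord],
      peak_times = as.numeric(t_draws)[ord]
    ),
    class = "kymograph"
  )
}

#' Programmed delay before aggregation cycle k + 1
#'
#' The inter-aggregation waiting time grows as a power of the cycle index,
#' `kpeak * k^p`; the fitted exponent (about 2.79) makes successive ATG13
#' translocations increasingly sparse as LC3 coverage of the mitochondrion
#' grows.
#'
#' @param k Completed cycle index (>= 1); vectorized.
#' @param kpeak Base delay coefficient (s).
#' @param p Growth exponent (dimensionless).
#' @return Delay in seconds.
#' @export
#' @examples
#' delay_for_cycle(2, 1, 2.79) / delay_for_cycle(1, 1, 2.79)  # 2^2.79
delay_for_cycle <- function(k, kpeak, p) {
  if (any(k < 1)) stop("cycle index k must be >= 1")
  kpeak * k^p
}

truncated_normal <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  draws <- stats::rnorm(n, mean, sd)
  while (any(draws <= 0)) {
    idx <- which(draws <= 0)
    draws[idx] <- stats::rnorm(length(idx), mean, sd)
  }
  draws
}

#' Simulate a single hybrid mitophagy event
#'
#' Cycle k: ATG13 accumulates for a sampled time-to-peak `t_k`
#' (Normal(t_mean, t_sd) truncated at 0), then is removed until it falls
#' below `1.05 * atg13_seed`; cumulative LC3 grows at `kprodLC3 * A` while
#' the cycle is active. After the cycle the system waits
#' [delay_for_cycle()] seconds. Before triggering the next accumulation the
#' engulfment condition `LC3(trigger - Tau) >= engulf_coeff * mt_diam` is
#' evaluated; once met, the event terminates. Per-phase dynamics use the
#' exact analytic solutions, so identical seeds give bit-identical output.
#'
#' @param params A [mitophagy_params()] object.
#' @param seed Integer seed (or `NULL` to continue the current RNG stream).
#' @param mt_diam Optional fixed mitochondrial diameter (micrometres);
#'   when `NULL` it is drawn once from the truncated normal in `params`.
#' @param dt Output grid step (s).
#' @param horizon Optional output horizon (s); the trajectory is padded at
#'   baseline after termination. Defaults to the termination time.
#' @param max_cycles Safety bound on the number of aggregation cycles.
#' @return An object of class `mitophagy_sim`: list with `trace` and `lc3`
#'   (data.frames `time_s`, `intensity_au`), `peak_num` (step series of
#'   completed-cycle counts), `peak_times`, `peak_delay_obs` (differences of
#'   successive peak times), `cycle_gaps` (programmed delays), `sampled_t`,
#'   `mt_diam`, `threshold`, `lc3_per_cycle`, `termination_time`.
#' @export
simulate_mitophagy <- function(params, seed = NULL, mt_diam = NULL, dt = 10,
                               horizon = NULL, max_cycles = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mt_diam)) {
    mt_diam <- truncated_normal(1, params$mt_diam_mean, params$mt_diam_sd)
  }
  stopifnot(mt_diam > 0)
  size <- if (params$area_threshold) mt_diam^2 else mt_diam
  threshold <- params$engulf_coeff * size
  if (params$kprodLC3 <= 0) {
    stop("engulfment cannot complete: kprodLC3 = 0 produces no LC3")
  }
  if (params$kremATG13 <= 0) {
    stop("ATG13 removal rate is zero; aggregation cycles cannot end")
  }
  A0 <- params$atg13_seed
  Ab <- 1.05 * A0
  kprod <- params$kprodATG13
  krem <- params$kremATG13
  m <- params$m

  segs <- list()   # per-segment bookkeeping for trajectory reconstruction
  peak_times <- numeric(0)
  gaps <- numeric(0)
  sampled_t <- numeric(0)
  lc3_per_cycle <- numeric(0)
  cum_lc3 <- 0
  cur <- 0
  k <- 0L
  termination_time <- NA_real_

  repeat {
    k <- k + 1L
    if (k > max_cycles) stop("max_cycles exceeded; engulfment cannot complete")
    t_k <- truncated_normal(1, params$t_mean, params$t_sd)
    Ap <- accum_solution(t_k, A0, kprod, m)
    if (!is.finite(Ap)) {
      stop("finite-time blow-up in the accumulation phase; check m and kprodATG13")
    }
    segs[[length(segs) + 1L]] <- list(
      type = "accum", t0 = cur, t1 = cur + t_k, A0 = A0, lc3_0 = cum_lc3
    )
    inc_acc <- params$kprodLC3 * accum_integral(t_k, A0, kprod, m)
    r_k <- if (Ap > Ab) log(Ap / Ab) / krem else 0
    segs[[length(segs) + 1L]] <- list(
      type = "decay", t0 = cur + t_k, t1 = cur + t_k + r_k, A0 = Ap,
      lc3_0 = cum_lc3 + inc_acc
    )
    inc_dec <- params$kprodLC3 * (Ap - max(Ab, Ap * exp(-krem * r_k))) / krem
    inc <- inc_acc + inc_dec
    if (inc <= 0) stop("engulfment cannot complete: zero LC3 deposited per cycle")
    cum_lc3 <- cum_lc3 + inc
    peak_times <- c(peak_times, cur + t_k)
    sampled_t <- c(sampled_t, t_k)
    lc3_per_cycle <- c(lc3_per_cycle, inc)
    cycle_end <- cur + t_k + r_k

    d_k <- delay_for_cycle(k, params$kpeak, params$p)
    # LC3 seen by the trigger, Tau seconds in the past; LC3 is flat during
    # gaps so only a Tau reaching back into the previous cycle matters
    eval_time <- cycle_end + d_k - params$Tau
    lc3_seen <- if (eval_time >= cycle_end) {
      cum_lc3
    } else if (eval_time <= 0) {
      0
    } else {
      eval_segments(segs, eval_time, params, what = "lc3")
    }
    if (lc3_seen >= threshold) {
      termination_time <- cycle_end
      break
    }
    segs[[length(segs) + 1L]] <- list(
      type = "gap", t0 = cycle_end, t1 = cycle_end + d_k, A0 = A0, lc3_0 = cum_lc3
    )
    gaps <- c(gaps, d_k)
    cur <- cycle_end + d_k
  }

  end_time <- if (is.null(horizon)) termination_time else max(horizon, termination_time)
  times <- seq(0, ceiling(end_time / dt) * dt, by = dt)
  A <- eval_segments(segs, times, params, what = "A")
  L <- eval_segments(segs, times, params, what = "lc3")
  counts <- vapply(times, function(x) sum(peak_times <= x), integer(1))

  structure(
    list(
      trace = data.frame(time_s = times, intensity_au = A),
      lc3 = data.frame(time_s = times, intensity_au = L),
      peak_num = data.frame(time_s = times, count = counts),
      peak_times = peak_times,
      peak_delay_obs = diff(peak_times),
      cycle_gaps = gaps,
      sampled_t = sampled_t,
      mt_diam = mt_diam,
      threshold = threshold,
      lc3_per_cycle = lc3_per_cycle,
      termination_time = termination_time
    ),
    class = "mitophagy_sim"
  )
}

eval_segments <- function(segs, times, params, what = c("A", "lc3")) {
  what <- match.arg(what)
  A0 <- params$atg13_seed
  out <- rep(if (what == "A") A0 else NA_real_, length(times))
  last_lc3 <- 0
  for (seg in segs) {
    idx <- times >= seg$t0 & times <= seg$t1
    s <- times[idx] - seg$t0
    if (seg$type == "accum") {
      if (what == "A") {
        out[idx] <- accum_solution(s, seg$A0, params$kprodATG13, params$m)
      } else {
        out[idx] <- seg$lc3_0 +
          params$kprodLC3 * accum_integral(s, seg$A0, params$kprodATG13, params$m)
      }
    } else if (seg$type == "decay") {
      if (what == "A") {
        out[idx] <- decay_solution(s, seg$A0, params$kremATG13, 1)
      } else {
        out[idx] <- seg$lc3_0 +
          params$kprodLC3 * seg$A0 * (1 - exp(-params$kremATG13 * s)) / params$kremATG13
      }
    } else {
      if (what == "A") out[idx] <- A0 else out[idx] <- seg$lc3_0
    }
    last_lc3 <- if (seg$type == "accum") {
      seg$lc3_0 + params$kprodLC3 *
        accum_integral(seg$t1 - seg$t0, seg$A0, params$kprodATG13, params$m)
    } else if (seg$type == "decay") {
      seg$lc3_0 + params$kprodLC3 * seg$A0 *
        (1 - exp(-params$kremATG13 * (seg$t1 - seg$t0))) / params$kremATG13
    } else {
      seg$lc3_0
    }
  }
  after <- times > segs[[length(segs)]]$t1
  if (what == "A") out[after] <- A0 else out[after] <- last_lc3
  if (what == "lc3") out[is.na(out)] <- 0
  out
}

#' Simulate a population of mitophagy events
#'
#' Diameters are drawn once per event from the truncated normal in `params`;
#' per-cycle times-to-peak are drawn within each event. Cycle-to-cycle
#' stochasticity makes the population lose peak synchronization over time.
#'
#' @param n Number of events (>= 2).
#' @param params A [mitophagy_params()] object.
#' @param seed Integer seed for the whole population.
#' @param dt,horizon,max_cycles Passed to [simulate_mitophagy()].
#' @return List of `mitophagy_sim` objects (class `mitophagy_population`).
#' @export
simulate_mitophagy_population <- function(n, params, seed = 1L, dt = 10,
                                          horizon = NULL, max_cycles = 1000L) {
  stopifnot(n >= 2)
  set.seed(seed)
  diams <- truncated_normal(n, params$mt_diam_mean, params$mt_diam_sd)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- simulate_mitophagy(
      params, seed = NULL, mt_diam = diams[i], dt = dt,
      horizon = horizon, max_cycles = max_cycles
    )
  }
  class(out) <- "mitophagy_population"
  out
}

#' Completed aggregation peaks by a checkpoint time
#'
#' @param result A `mitophagy_sim` object.
#' @param time Checkpoint (s), e.g. 510 or 910; the mid-run checkpoint may
#'   equally be taken at 500 s.
#' @return Integer count of peaks with peak time `<= time`.
#' @export
peaks_completed <- function(result, time) {
  sum(result$peak_times <= time)
}
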