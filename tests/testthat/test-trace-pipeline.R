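two_pulse_traces <- function() {
  t1 <- seq(0, 300, by = 10)
  mk <- function(id, peak) {
    data.frame(repeat_id = id, condition = "starvation", time_s = t1,
               intensity_au = exp(-((t1 - peak) / 40)^2),
               stringsAsFactors = FALSE)
  }
  rbind(mk("a", 50), mk("b", 120))
}

test_that("peak synchronization moves every argmax to zero and is idempotent", {
  sync <- synchronize_on_peak(two_pulse_traces())
  for (id in c("a", "b")) {
    tr <- sync[sync$repeat_id == id, ]
    expect_equal(tr$time_s[which.max(tr$intensity_au)], 0)
  }
  expect_identical(synchronize_on_peak(sync), sync)
  flat <- data.frame(repeat_id = "f", condition = "x",
                     time_s = 0:9 * 10, intensity_au = rep(1, 10))
  expect_error(synchronize_on_peak(flat), "no peak")
})

test_that("peak detection recovers the peaks of a noiseless sine", {
  t <- seq(0, 1000, by = 5)
  trace <- data.frame(time_s = t, intensity_au = sin(2 * pi * t / 200) + 2)
  train <- detect_peaks(trace)
  expected <- 50 + 200 * (0:4)
  expect_identical(nrow(train$upper_peaks), 5L)
  expect_equal(train$upper_peaks$time_s, expected, tolerance = 1e-6)
  expect_equal(train$upper_delays, rep(200, 4), tolerance = 1e-6)
  expect_identical(nrow(train$troughs), 4L)
  # troughs alternate between peaks
  expect_true(all(train$troughs$time_s > head(train$upper_peaks$time_s, -1) &
                    train$troughs$time_s < train$upper_peaks$time_s[-1]))
})

test_that("monotone traces yield at most one peak and no delays", {
  t <- seq(0, 200, by = 10)
  up <- data.frame(time_s = t, intensity_au = t / 200)
  train <- detect_peaks(up)
  expect_lte(nrow(train$upper_peaks), 1L)
  expect_length(train$upper_delays, 0)
})

test_that("regularization flattens a known exponential bleaching decline", {
  t <- seq(0, 900, by = 10)
  clean <- 1 + 0.5 * sin(2 * pi * t / 150)
  bleached <- data.frame(time_s = t,
                         intensity_au = clean * exp(-t / 600))
  fixed <- regularize_decline(bleached)
  troughs <- atg13dyn:::local_maxima(-fixed$intensity_au)
  slope <- stats::coef(stats::lm(fixed$intensity_au[troughs] ~
                                   fixed$time_s[troughs]))[2]
  expect_lt(abs(slope), 1e-3)
  # flat envelope input passes through nearly unchanged
  flat <- data.frame(time_s = t, intensity_au = clean)
  out <- regularize_decline(flat)
  expect_equal(out$intensity_au, clean, tolerance = 0.05)
})

test_that("population summary reproduces hand-computed moments", {
  tr <- data.frame(
    repeat_id = rep(c("a", "b", "c"), each = 2),
    time_s = rep(c(0, 10), 3),
    intensity_au = c(1, 4, 2, 5, 3, 9)
  )
  s <- summarize_population(tr)
  expect_equal(s$mean, c(2, 6))
  expect_equal(s$sd, c(1, sqrt(7)))
  expect_equal(s$n_per_timepoint, c(3L, 3L))
  expect_equal(s$ci95_halfwidth[1], stats::qt(0.975, 2) * 1 / sqrt(3))
  same <- tr; same$intensity_au <- rep(c(1, 2), 3)
  s2 <- summarize_population(same)
  expect_equal(s2$sd, c(0, 0))
  expect_equal(s2$ci95_halfwidth, c(0, 0))
  expect_error(summarize_population(tr[-c(1, 3), ]), "fewer than 2")
})

test_that("mitophagy preparation drops injected irregular traces and trims to 3 repeats", {
  bundle <- gen_mitophagy_population(23, seed = 5, n_irregular = 6)
  prepared <- mitophagy_prepare(bundle$traces)
  ids <- unique(prepared$repeat_id)
  expect_length(ids, 17L)
  expect_false(any(bundle$irregular_ids %in% ids))
  counts <- table(prepared$time_s)
  expect_gte(min(counts), 3)
  prov <- attr(prepared, "provenance")
  expect_identical(prov$steps, c("spline", "align", "restore", "filter", "trim"))
  expect_length(prov$dropped, 6L)
})

test_that("alignment leaves identical traces unshifted and recovers injected shifts", {
  pd <- default_mitophagy_params(t_sd = 0)
  base <- simulate_mitophagy(pd, mt_diam = 0.9)$trace
  mk <- function(id, shift_frames) {
    data.frame(repeat_id = id, condition = "ivm",
               time_s = base$time_s + 10 * shift_frames,
               intensity_au = base$intensity_au, stringsAsFactors = FALSE)
  }
  same <- rbind(mk("a", 0), mk("b", 0), mk("c", 0), mk("d", 0))
  out <- mitophagy_prepare(same)
  expect_true(all(attr(out, "provenance")$shifts == 0))
  shifted <- rbind(mk("a", 0), mk("b", 2), mk("c", -1), mk("d", 0))
  out2 <- mitophagy_prepare(shifted)
  sh <- attr(out2, "provenance")$shifts
  # relative shifts recovered up to a common offset, within one frame
  rel <- sh - sh["a"]
  expect_lte(max(abs(rel - c(a = 0, b = -20, c = 10, d = 0))), 10)
})

test_that("count-diameter correlation matches the hand-computed toy value", {
  r <- correlate_counts_diameters(c(2, 1, 3), c(1, 2, 3))
  expect_equal(r$r, 0.5)
  perfect <- correlate_counts_diameters(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(perfect$r, 1)
  expect_error(correlate_counts_diameters(c(2, 2, 2), c(1, 2, 3)),
               "zero variance")
  expect_true(all(c("diameter", "fit", "lwr", "upr") %in% names(r$band)))
})

test_that("diameter statistics average at least eight measurements per event", {
  tab <- gen_diameters(17, seed = 2)
  expect_identical(nrow(tab), 17L * 8L)
  st <- diameter_stats(tab)
  expect_identical(st$n_events, 17L)
  expect_true(all(st$per_event_means > 0))
  expect_false(is.na(st$shapiro_p))
  short <- tab[tab$event_id != "event_01" |
                 seq_len(nrow(tab)) %in% 1:3, ]
  expect_warning(diameter_stats(short), "fewer than 8")
})

test_that("first-peak extraction cuts at the first trough and synchronizes", {
  pd <- default_mitophagy_params(t_sd = 0)
  pop <- simulate_mitophagy_population(3, default_mitophagy_params(), seed = 9)
  traces <- population_traces(pop)
  fp <- extract_first_peak(traces)
  for (id in unique(fp$repeat_id)) {
    tr <- fp[fp$repeat_id == id, ]
    expect_equal(tr$time_s[which.max(tr$intensity_au)], 0)
    i <- as.integer(sub("r", "", id))
    # the cut stops before the second true aggregation peak
    expect_lt(max(tr$time_s), pop[[i]]$peak_times[2] - pop[[i]]$peak_times[1])
  }
})
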