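test_that("eventless m = 0 trajectory matches the closed-form exponential relaxation", {
  p <- nonselective_params(0.02, 0.005, m = 0, atg13_seed = 0.01)
  tc <- simulate_nonselective(p, model_variant(4), horizon = 600, dt = 5)
  expected <- with(p, kprodATG13 / kremATG13 +
                     (atg13_seed - kprodATG13 / kremATG13) *
                       exp(-kremATG13 * tc$time_s))
  expect_equal(tc$intensity_au, expected, tolerance = 1e-6)
})

test_that("trajectories agree with an independent stiff ODE integrator", {
  skip_if_not_installed("deSolve")
  times <- seq(0, 800, by = 10)
  # eventless, general m: Bernoulli closed form vs lsoda
  p <- default_nonselective_params()
  A <- atg13dyn:::nonselective_solution(times, p, model_variant(6), FALSE)
  ode_fun <- function(t, y, parms) {
    list(p$kprodATG13 * y^p$m - p$kremATG13 * y)
  }
  num <- deSolve::lsoda(c(A = p$atg13_seed), times, ode_fun, NULL,
                        rtol = 1e-10, atol = 1e-12)[, "A"]
  expect_equal(A, unname(num), tolerance = 1e-6)
  # event-based: piecewise analytic vs lsoda with a hard switch at t
  Aev <- atg13dyn:::nonselective_solution(times, p, model_variant(3), FALSE)
  acc <- deSolve::lsoda(c(A = p$atg13_seed), times[times <= p$t],
                        function(t, y, .) list(p$kprodATG13 * y^p$m), NULL,
                        rtol = 1e-10, atol = 1e-12)[, "A"]
  Ap <- acc[length(acc)]
  dec <- deSolve::lsoda(c(A = unname(Ap)), times[times >= p$t] - p$t,
                        function(t, y, .) list(-p$kremATG13 * y), NULL,
                        rtol = 1e-10, atol = 1e-12)[, "A"]
  expect_equal(Aev[times < p$t], unname(acc[-length(acc)]), tolerance = 1e-6)
  expect_equal(Aev[times >= p$t], unname(dec), tolerance = 1e-6)
})

test_that("event-based pulses are unimodal with the maximum at the event time", {
  for (t_ev in c(150, 300, 450)) {
    p <- default_nonselective_params(t = t_ev)
    tc <- simulate_nonselective(p, model_variant(3), horizon = 900, dt = 10)
    peak_at <- tc$time_s[which.max(tc$intensity_au)]
    expect_lte(abs(peak_at - t_ev), 10)
    before <- tc$intensity_au[tc$time_s <= peak_at]
    after <- tc$intensity_au[tc$time_s >= peak_at]
    expect_true(all(diff(before) >= 0))
    expect_true(all(diff(after) <= 0))
  }
  expect_error(simulate_nonselective(default_nonselective_params(t = 500),
                                     model_variant(1), horizon = 400),
               "horizon")
})

test_that("zero production leaves nothing to aggregate", {
  # no production and no removal: the seed persists unchanged
  p0 <- nonselective_params(0, 0, m = 1, t = 100, atg13_seed = 0.01)
  for (vid in c(2, 5)) {
    tc <- simulate_nonselective(p0, model_variant(vid), horizon = 300)
    expect_equal(tc$intensity_au, rep(0.01, nrow(tc)))
  }
  # with removal active the seed can only decay: no pulse ever forms
  p1 <- nonselective_params(0, 0.01, m = 1, t = 100, atg13_seed = 0.01)
  tc1 <- simulate_nonselective(p1, model_variant(2), horizon = 300)
  expect_true(all(diff(tc1$intensity_au) <= 0))
  expect_lte(max(tc1$intensity_au), 0.01)
})

test_that("kymographs are normalized, sorted by decreasing peak time, and reproducible", {
  dist <- list(type = "normal", mean = 300, sd = 60)
  k1 <- simulate_kymograph(35, dist, default_nonselective_params(), seed = 4)
  k2 <- simulate_kymograph(35, dist, default_nonselective_params(), seed = 4)
  expect_identical(k1, k2)
  expect_equal(dim(k1$matrix), c(35L, length(k1$times)))
  expect_equal(apply(k1$matrix, 1, min), rep(0, 35))
  expect_equal(apply(k1$matrix, 1, max), rep(1, 35))
  argmax_t <- k1$times[apply(k1$matrix, 1, which.max)]
  expect_true(all(diff(argmax_t) <= 0))
})

test_that("degenerate zero-sd peak-time distribution keeps stable repeat order", {
  k <- simulate_kymograph(5, list(type = "normal", mean = 200, sd = 0),
                          default_nonselective_params(), seed = 1)
  expect_identical(k$row_order, sprintf("sim_%02d", 1:5))
  expect_equal(max(abs(sweep(k$matrix, 2, k$matrix[1, ]))), 0)
})

test_that("log-normal peak-time sampling follows the generating distribution", {
  set.seed(99)
  draws <- sample_peak_times(1e4, list(type = "lognormal",
                                       meanlog = log(200), sdlog = 0.35))
  ks <- stats::ks.test(draws, stats::plnorm, log(200), 0.35)
  expect_gt(ks$p.value, 0.01)
  set.seed(99)
  tn <- sample_peak_times(1e4, list(type = "normal", mean = 30, sd = 40))
  expect_true(all(tn > 0))
  expect_gt(attr(tn, "n_resampled"), 0)
})

test_that("cycle delay law is an exact power of the cycle index", {
  expect_equal(delay_for_cycle(2, 1, 2.79) / delay_for_cycle(1, 1, 2.79),
               2^2.79)
  expect_equal(delay_for_cycle(1:5, 2, 0), rep(2, 5))
  expect_equal(delay_for_cycle(3, 2, 3), 54)
  expect_error(delay_for_cycle(0, 1, 2), ">= 1")
})

test_that("a vanishing mitochondrion terminates after a single cycle", {
  p <- default_mitophagy_params(t_sd = 0)
  s <- simulate_mitophagy(p, mt_diam = 1e-6)
  expect_identical(length(s$peak_times), 1L)
  expect_true(is.finite(s$termination_time))
})

test_that("doubling the engulfment load doubles the cycle count at fixed deposition", {
  p1 <- default_mitophagy_params(t_sd = 0)
  s1 <- simulate_mitophagy(p1, mt_diam = 0.9)
  p2 <- default_mitophagy_params(t_sd = 0, engulf_coeff = 2 * p1$engulf_coeff)
  s2 <- simulate_mitophagy(p2, mt_diam = 0.9)
  expect_lte(abs(length(s2$peak_times) - 2 * length(s1$peak_times)), 1)
})

test_that("mitophagy simulation respects its structural invariants", {
  p <- default_mitophagy_params()
  s <- simulate_mitophagy(p, seed = 21)
  expect_true(all(diff(s$peak_num$count) >= 0))
  expect_true(all(diff(s$lc3$intensity_au) >= -1e-12))
  expect_true(is.finite(s$termination_time))
  # cycle-count bound from the least productive cycle
  expect_lte(length(s$peak_times),
             ceiling(s$threshold / min(s$lc3_per_cycle)))
  # deterministic version: realized inter-peak delays strictly increase
  sd0 <- simulate_mitophagy(default_mitophagy_params(t_sd = 0), mt_diam = 0.9)
  expect_true(all(diff(sd0$peak_delay_obs) > 0))
  # engulfment that can never complete is refused
  expect_error(simulate_mitophagy(default_mitophagy_params(kprodLC3 = 0),
                                  mt_diam = 0.9),
               "cannot complete")
})

test_that("identical seeds give bit-identical mitophagy populations", {
  p <- default_mitophagy_params()
  a <- simulate_mitophagy_population(4, p, seed = 13)
  b <- simulate_mitophagy_population(4, p, seed = 13)
  expect_identical(a, b)
  c <- simulate_mitophagy_population(4, p, seed = 14)
  expect_false(identical(a, c))
})

test_that("populations desynchronize: later peak times spread more across events", {
  p <- default_mitophagy_params()
  pop <- simulate_mitophagy_population(200, p, seed = 8)
  counts <- vapply(pop, function(s) length(s$peak_times), integer(1))
  # restrict to events reaching at least 4 cycles so peak k exists
  sub <- pop[counts >= 4]
  expect_gte(length(sub), 100)
  vars <- vapply(1:4, function(k) {
    stats::var(vapply(sub, function(s) s$peak_times[k], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("expected cycle count is non-decreasing in the diameter", {
  p <- default_mitophagy_params(t_sd = 0)
  diams <- c(0.3, 0.6, 0.9, 1.2, 1.5)
  counts <- vapply(diams, function(d) {
    length(simulate_mitophagy(p, mt_diam = d)$peak_times)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})
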