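# Analytic phase solutions for the one-dimensional ATG13 rate laws.
# All solvers are vectorized over s (time since phase start, s >= 0) and
# return Inf where a finite-time blow-up has been passed (m > 1 growth).

# dA/dt = k * A^m, A(0) = A0
accum_solution <- function(s, A0, k, m) {
  if (k == 0) return(rep(A0, length(s)))
  if (abs(m - 1) < 1e-9) return(A0 * exp(k * s))
  base <- A0^(1 - m) + (1 - m) * k * s
  out <- rep(Inf, length(s))
  ok <- base > 0
  out[ok] <- base[ok]^(1 / (1 - m))
  out
}

# int_0^s A(u) du for the accumulation solution above
accum_integral <- function(s, A0, k, m) {
  if (k == 0) return(A0 * s)
  if (abs(m - 1) < 1e-9) return(A0 * (exp(k * s) - 1) / k)
  if (abs(m - 2) < 1e-9) {
    c0 <- 1 / A0
    base <- c0 - k * s
    out <- rep(Inf, length(s))
    ok <- base > 0
    out[ok] <- log(c0 / base[ok]) / k
    return(out)
  }
  base <- A0^(1 - m) + (1 - m) * k * s
  out <- rep(Inf, length(s))
  ok <- base > 0
  ex <- (2 - m) / (1 - m)
  out[ok] <- (base[ok]^ex - A0^(2 - m)) / ((2 - m) * k)
  out
}

# dA/dt = -k * A^ord, A(0) = A0 (removal phase; ord = 1 is exponential decay)
decay_solution <- function(s, A0, k, ord = 1) {
  if (k == 0 || A0 == 0) return(rep(A0, length(s)))
  if (abs(ord - 1) < 1e-9) return(A0 * exp(-k * s))
  base <- A0^(1 - ord) - (1 - ord) * k * s
  if (ord < 1) {
    # reaches zero in finite time
    return(ifelse(base > 0, base^(1 / (1 - ord)), 0))
  }
  base^(1 / (1 - ord))
}

# dA/dt = kprod * A^m - krem * A (Bernoulli form; covers every m >= 0),
# the eventless model with first-order removal
eventless_solution <- function(s, A0, kprod, krem, m) {
  if (krem == 0) return(accum_solution(s, A0, kprod, m))
  if (kprod == 0) return(decay_solution(s, A0, krem, 1))
  if (abs(m - 1) < 1e-9) return(A0 * exp((kprod - krem) * s))
  ratio <- kprod / krem
  u <- ratio + (A0^(1 - m) - ratio) * exp(-(1 - m) * krem * s)
  out <- rep(Inf, length(s))
  ok <- u > 0
  out[ok] <- u[ok]^(1 / (1 - m))
  out
}

# fixed-step RK4 fallback for rate-law configurations without a closed form
# (eventless model with a non-first-order removal exponent)
rk4_path <- function(times, A0, deriv, dt_internal = 0.5) {
  stopifnot(all(diff(times) > 0))
  grid <- sort(unique(c(seq(min(times), max(times), by = dt_internal), times)))
  A <- numeric(length(grid))
  A[1] <- A0
  for (i in seq_len(length(grid) - 1L)) {
    h <- grid[i + 1L] - grid[i]
    a <- A[i]
    if (!is.finite(a) || a > 1e12) {
      A[(i + 1L):length(grid)] <- Inf
      break
    }
    k1 <- deriv(a)
    k2 <- deriv(max(a + h / 2 * k1, 0))
    k3 <- deriv(max(a + h / 2 * k2, 0))
    k4 <- deriv(max(a + h * k3, 0))
    A[i + 1L] <- max(a + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  A[match(times, grid)]
}

# A(time) for any nonselective variant; time measured from initiation
nonselective_solution <- function(times, params, variant, wortmannin = FALSE) {
  stopifnot(all(is.finite(times)), all(times >= 0))
  sc <- wortmannin_scales(params, wortmannin, variant)
  kprod <- sc$acc * params$kprodATG13
  krem <- sc$rem * params$kremATG13
  ord <- if (is.null(params$removal_order)) 1 else params$removal_order
  A0 <- params$atg13_seed
  if (variant$event_based) {
    t_ev <- params$t
    if (is.na(t_ev) || t_ev <= 0) stop("event-based variants require t > 0")
    A <- numeric(length(times))
    pre <- times < t_ev
    A[pre] <- accum_solution(times[pre], A0, kprod, params$m)
    Ap <- accum_solution(t_ev, A0, kprod, params$m)
    A[!pre] <- decay_solution(times[!pre] - t_ev, Ap, krem, ord)
    A
  } else {
    if (abs(ord - 1) < 1e-9) {
      eventless_solution(times, A0, kprod, krem, params$m)
    } else {
      deriv <- function(a) kprod * a^params$m - krem * a^ord
      tt <- sort(unique(c(0, times)))
      path <- rk4_path(tt, A0, deriv)
      path[match(times, tt)]
    }
  }
}
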