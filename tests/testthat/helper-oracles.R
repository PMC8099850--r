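# Shared fixtures and independent oracles. Every oracle deliberately takes a
# different computational route than the implementation it checks.

protocol_schedule <- function() {
  parse_frame_scheme("1x15,3x5,3x10,2x30,3x60,2x150,2x300,7x600")
}

fixture_ref <- function(schedule = protocol_schedule()) {
  generate_reference_tac(schedule)
}

# Riemann-sum convolution of the piecewise-linear interpolant (anchored at
# (0, 0)) with exp(-theta t); brute-force quadrature, no analytic segments.
oracle_conv <- function(ref, theta, dt = 0.005) {
  mid <- (ref$schedule$starts + ref$schedule$durations / 2) / 60
  f <- stats::approxfun(c(0, mid), c(0, ref$values), rule = 2)
  vapply(mid, function(t) {
    s <- seq(0, t, length.out = max(2L, ceiling(t / dt) + 1L))
    g <- f(s) * exp(-theta * (t - s))
    (sum(g) - (g[1] + g[length(g)]) / 2) * (s[2] - s[1])
  }, numeric(1))
}

# One-tissue ODE route for the SRTM target curve: integrate
# du/dt = (k2 - R1*k2a) * C_R(t) - k2a * u with C_T = R1*C_R + u.
oracle_srtm_ode <- function(ref, R1, k2, bp_nd) {
  k2a <- k2 / (1 + bp_nd)
  mid <- (ref$schedule$starts + ref$schedule$durations / 2) / 60
  cr <- stats::approxfun(c(0, mid), c(0, ref$values), rule = 2)
  out <- deSolve::lsoda(
    y = c(u = 0), times = c(0, mid),
    func = function(t, y, p) list((k2 - R1 * k2a) * cr(t) - k2a * y[1]),
    rtol = 1e-10, atol = 1e-12)
  R1 * ref$values + out[-1, "u"]
}

# Continuous-theta nonlinear SRTM2 fit using its own numeric convolution:
# golden-section search over theta with the closed-form R1 profiled out.
oracle_srtm2_nls <- function(target, ref, k2_prime,
                             interval = c(0.006, 0.6)) {
  rss <- function(theta) {
    B <- ref$values + (k2_prime - theta) * oracle_conv(ref, theta)
    r1 <- sum(B * target$values) / sum(B * B)
    sum((target$values - r1 * B)^2)
  }
  opt <- stats::optimize(rss, interval = interval, tol = 1e-7)
  theta <- opt$minimum
  B <- ref$values + (k2_prime - theta) * oracle_conv(ref, theta)
  list(R1 = sum(B * target$values) / sum(B * B), theta = theta,
       rss = opt$objective)
}

# Full-permutation Mann-Whitney oracle: bitmask subset enumeration and U by
# direct pair counting (ties count one half), independent of rank sums.
oracle_mwu_p <- function(a, b) {
  pair_u <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  pooled <- c(a, b)
  n <- length(pooled)
  n1 <- length(a)
  u_obs <- pair_u(a, b)
  us <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(bits) != n1) next
    us <- c(us, pair_u(pooled[bits], pooled[!bits]))
  }
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# noisy target TAC matrix under the count-statistics noise shape
noisy_tac_matrix <- function(mu, schedule, noise_level, n) {
  d <- schedule$durations
  sd <- noise_level * abs(mu) * sqrt(mean(d) / d)
  matrix(stats::rnorm(length(mu) * n, mean = mu, sd = sd), ncol = n)
}
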