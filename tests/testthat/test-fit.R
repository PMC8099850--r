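# Basis-function fitters: recovery, coupling, and optimality properties.

test_that("RPM recovers noise-free parameters exactly when k2a lies on the grid", {
  ref <- fixture_ref()
  basis <- srtm_basis(ref)
  for (j in c(30, 45, 60)) {
    theta <- basis$thetas[j]
    truth <- c(R1 = 0.85, bp = 0.6)
    k2 <- theta * (1 + truth[["bp"]])
    tgt <- srtm_forward(ref, truth[["R1"]], k2, truth[["bp"]])
    fit <- fit_rpm(tgt, basis)
    expect_equal(coef(fit)[["R1"]], truth[["R1"]], tolerance = 1e-6)
    expect_equal(coef(fit)[["k2a"]], theta, tolerance = 1e-9)
    expect_equal(coef(fit)[["BP_ND"]], truth[["bp"]], tolerance = 1e-6)
    expect_true(fit$valid)
  }
})

test_that("a target identical to the reference fits to R1 = 1, BP_ND = 0", {
  ref <- fixture_ref()
  basis <- srtm_basis(ref)
  fit <- fit_rpm(tac(ref$schedule, ref$values), basis)
  expect_equal(coef(fit)[["R1"]], 1, tolerance = 1e-4)
  expect_equal(coef(fit)[["BP_ND"]], 0, tolerance = 0.05)  # grid resolution
})

test_that("all-zero targets and an all-zero reference are flagged invalid", {
  ref <- fixture_ref()
  basis <- srtm_basis(ref)
  fit <- fit_rpm(tac(ref$schedule, rep(0, 23)), basis)
  expect_false(fit$valid)

  zero_ref <- tac(ref$schedule, rep(0, 23))
  arr <- array(rep(ref$values, each = 8), c(2, 2, 2, 23))
  img <- dynamic_image(arr, ref$schedule)
  maps <- fit_rpm(img, srtm_basis(zero_ref))
  expect_true(all(!maps$validity))
  expect_true(all(is.nan(maps$R1)))
})

test_that("coupled k2' is the median of k2/R1 over voxels with BP_ND above threshold", {
  ref <- fixture_ref()
  basis <- srtm_basis(ref)
  sch <- ref$schedule
  # voxels built with k2a on the grid so RPM recovery is exact:
  # bp = R1 * k2prime / theta - 1
  mk_img <- function(params, theta) {
    arr <- array(0, c(length(params), 1, 1, 23))
    for (i in seq_along(params)) {
      p <- params[[i]]  # (R1, k2prime)
      bp <- p[1] * p[2] / theta - 1
      arr[i, 1, 1, ] <- srtm_forward(ref, p[1], p[1] * p[2], bp)$values
    }
    dynamic_image(arr, sch)
  }
  theta <- basis$thetas[44]  # ~0.06 min^-1
  k2p <- 0.15
  # three voxels sharing k2' = 0.15 exactly
  img <- mk_img(list(c(0.8, k2p), c(0.9, k2p), c(1.0, k2p)), theta)
  maps <- fit_rpm(img, basis)
  expect_equal(estimate_k2_prime(maps), k2p, tolerance = 1e-9)

  # distinct k2' values {0.10, 0.15, 0.20}: median by enumeration
  img2 <- mk_img(list(c(0.9, 0.10), c(0.9, 0.15), c(0.9, 0.20)), theta)
  maps2 <- fit_rpm(img2, basis)
  expect_equal(estimate_k2_prime(maps2), 0.15, tolerance = 1e-9)

  # no voxel exceeds the (strict) threshold -> explicit error
  img3 <- dynamic_image(aperm(array(c(srtm_forward(ref, 0.9, 0.135, 0)$values,
                                      srtm_forward(ref, 0.95, 0.14, 0.03)$values),
                                    c(23, 1, 1, 2)), c(4, 2, 3, 1)), sch)
  maps3 <- fit_rpm(img3, basis)
  expect_error(estimate_k2_prime(maps3), "BP_ND")
  # strictness: voxels at exactly the threshold do not qualify
  expect_error(estimate_k2_prime(maps, bp_threshold = 1e9), "BP_ND")
})

test_that("SRTM2 recovers R1 exactly when k2 = R1 * k2' and k2a is on the grid", {
  ref <- fixture_ref()
  basis <- srtm_basis(ref)
  k2p <- 0.15
  for (R1 in c(0.8, 0.93, 1.05)) {
    k2 <- R1 * k2p
    theta_star <- basis$thetas[which.min(abs(basis$thetas - k2 / 1.5))]
    bp <- k2 / theta_star - 1
    tgt <- srtm_forward(ref, R1, k2, bp)
    fit <- fit_srtm2(tgt, basis, k2_prime = k2p)
    expect_equal(coef(fit)[["R1"]], R1, tolerance = 1e-6)
    expect_equal(coef(fit)[["k2a"]], theta_star, tolerance = 1e-9)
  }
})

test_that("SRTM2 maps satisfy BP_ND = R1 * k2' / k2a - 1 identically where valid", {
  ref <- fixture_ref()
  basis <- srtm_basis(ref)
  set.seed(7)
  arr <- array(0, c(4, 3, 1, 23))
  for (i in seq_len(12)) {
    R1 <- runif(1, 0.7, 1.0)
    bp <- runif(1, 0.1, 1.5)
    mu <- srtm_forward(ref, R1, R1 * 0.15, bp)$values
    arr[((i - 1) %% 4) + 1, ((i - 1) %/% 4) + 1, 1, ] <-
      mu * (1 + rnorm(23, sd = 0.03))
  }
  maps <- fit_srtm2(dynamic_image(arr, ref$schedule), basis,
                    k2_prime = 0.15)
  sel <- maps$validity
  expect_true(any(sel))
  expect_equal(maps$bp_nd[sel],
               maps$R1[sel] * maps$k2_prime / maps$k2a[sel] - 1,
               tolerance = 1e-6)
  expect_equal(maps$k2_prime, 0.15)
})

test_that("RPM and SRTM2 give identical R1 on noise-free data when k2' matches", {
  ref <- fixture_ref()
  basis <- srtm_basis(ref)
  theta <- basis$thetas[50]
  R1 <- 0.88
  bp <- 0.7
  k2 <- theta * (1 + bp)
  tgt <- srtm_forward(ref, R1, k2, bp)
  rpm <- fit_rpm(tgt, basis)
  srtm2 <- fit_srtm2(tgt, basis, k2_prime = k2 / R1)
  expect_equal(coef(srtm2)[["R1"]], coef(rpm)[["R1"]], tolerance = 1e-8)
})

test_that("grid-restricted RSS bounds the continuous fit from above and the gap shrinks", {
  ref <- fixture_ref()
  k2p <- 0.15
  bases <- lapply(c(25, 100, 400), function(nt)
    srtm_basis(ref, n_theta = nt))
  set.seed(99)
  gaps <- matrix(0, nrow = 8, ncol = 3)
  for (r in 1:8) {
    R1 <- runif(1, 0.75, 1.0)
    mu <- srtm_forward(ref, R1, R1 * k2p, runif(1, 0.2, 1.2))$values
    y <- tac(ref$schedule, mu * (1 + rnorm(23, sd = 0.04)))
    cont <- oracle_srtm2_nls(y, ref, k2p)
    for (j in 1:3) {
      fit <- fit_srtm2(y, bases[[j]], k2_prime = k2p)
      # the grid optimum can never beat the continuous optimum
      expect_gte(fit$rss, cont$rss - 1e-6 * cont$rss)
      gaps[r, j] <- fit$rss - cont$rss
    }
  }
  # the mean optimality gap vanishes as the grid is refined
  mg <- colMeans(gaps)
  expect_true(all(diff(mg) < 0))
  expect_lt(mg[3], mg[1] / 4)
})

test_that("with 5% proportional noise the mean R1 is within 2% and noise shrinks the spread", {
  ref <- fixture_ref()
  basis <- srtm_basis(ref)
  R1 <- 0.9
  k2p <- 0.15
  mu <- srtm_forward(ref, R1, R1 * k2p, 0.5)$values
  est <- function(noise, n = 300, seed = 123) {
    set.seed(seed)
    Y <- noisy_tac_matrix(mu, ref$schedule, noise, n)
    img <- dynamic_image(array(t(Y), c(n, 1, 1, 23)), ref$schedule)
    maps <- fit_srtm2(img, basis, k2_prime = k2p)
    maps$R1[maps$validity]
  }
  r5 <- est(0.05)
  expect_lt(abs(mean(r5) - R1) / R1, 0.02)
  r25 <- est(0.025)
  expect_lt(stats::sd(r25), stats::sd(r5))
})

test_that("fit contracts: schedule mismatch, bad weights, missing k2'", {
  ref <- fixture_ref()
  basis <- srtm_basis(ref)
  short <- parse_frame_scheme("5x60")
  expect_error(fit_rpm(tac(short, rep(1, 5)), basis), "schedule")
  tgt <- tac(ref$schedule, ref$values)
  expect_error(srtm_fit(tgt, basis, method = "srtm2"), "k2_prime")
  expect_error(fit_srtm2(tgt, basis, k2_prime = -1), "k2_prime")
  expect_error(srtm_fit(tgt, basis, method = "rpm",
                        weights = rep(-1, 23)), "weights")
})
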