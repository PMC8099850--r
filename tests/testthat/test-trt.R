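# Test-retest statistics: identities, hand-computed values, oracles.

test_that("percent TRT variability matches hand arithmetic and its identities", {
  expect_equal(trt_variability(0.9, 0.9), 0)
  # group-mean worked example: |0.93-0.91| / (0.5*1.84) * 100
  expect_equal(trt_variability(0.93, 0.91), 2.1739, tolerance = 1e-4)
  # symmetry and scale invariance over random pairs
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 0.5, 1.2)
    b <- runif(1, 0.5, 1.2)
    expect_equal(trt_variability(a, b), trt_variability(b, a))
    expect_equal(trt_variability(3.7 * a, 3.7 * b), trt_variability(a, b))
    expect_gte(trt_variability(a, b), 0)
  }
  expect_error(trt_variability(1, -1), "non-zero")
})

make_obs <- function(test, retest, subjects, regions, vol = NULL,
                     group = "CU", amyloid = "negative") {
  d <- expand.grid(subject = subjects, region = regions,
                   stringsAsFactors = FALSE)
  if (is.null(vol)) vol <- rep(1000, length(regions))
  d$volume_mm3 <- vol[match(d$region, regions)]
  d$test <- test
  d$retest <- retest
  d$group <- group
  d$amyloid_status <- amyloid
  d
}

test_that("regional TRT table averages subjects per region; global row uses composites", {
  # 2 subjects, 1 region with TRT 2% and 4% -> mean 3%
  t1 <- 1.0; r1 <- t1 * (1 - 0.02 / (1 + 0.01))  # TRT(t1, r1) = 2%
  t2 <- 1.0; r2 <- t2 * (1 - 0.04 / (1 + 0.02))  # TRT(t2, r2) = 4%
  obs <- data.frame(subject = c("s1", "s2"), region = "r",
                    volume_mm3 = 1000, test = c(t1, t2),
                    retest = c(r1, r2))
  expect_equal(trt_variability(t1, r1), 2)
  expect_equal(trt_variability(t2, r2), 4)
  tab <- regional_trt_table(obs)
  expect_equal(tab$mean_trt_pct[tab$region == "r"], 3)

  # all T == R -> all zeros; single subject -> TRT verbatim
  obs2 <- make_obs(0.9, 0.9, c("s1", "s2"), c("a", "b"))
  expect_equal(regional_trt_table(obs2)$mean_trt_pct, rep(0, 3))
  obs3 <- data.frame(subject = "s1", region = c("a", "b"),
                     volume_mm3 = c(1000, 3000),
                     test = c(0.93, 0.9), retest = c(0.91, 0.9))
  tab3 <- regional_trt_table(obs3)
  expect_equal(tab3$mean_trt_pct[tab3$region == "a"],
               trt_variability(0.93, 0.91))
  # global row comes from the volume-weighted composite, not the TRT mean
  Tc <- (1000 * 0.93 + 3000 * 0.9) / 4000
  Rc <- (1000 * 0.91 + 3000 * 0.9) / 4000
  expect_equal(tab3$mean_trt_pct[tab3$region == composite_region_name()],
               trt_variability(Tc, Rc))
  expect_error(regional_trt_table(obs3[0, ]), "non-empty")
})

test_that("volume-TRT regression recovers exact linear and null relationships", {
  regions <- paste0("r", 1:4)
  vols <- c(1000, 2000, 3000, 4000)
  # TRT exactly linear in volume: craft per-region TRT = 4,3,2,1 %
  trt_target <- c(4, 3, 2, 1)
  retest <- 0.9 * (1 - trt_target / 100 / (1 + trt_target / 200))
  obs <- data.frame(subject = "s1", region = regions, volume_mm3 = vols,
                    test = 0.9, retest = retest)
  obs <- rbind(obs, transform(obs, subject = "s2"))
  res <- volume_trt_correlation(obs)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_lt(res$slope, 0)

  # constant TRT across regions -> R^2 = 0
  obs0 <- data.frame(subject = "s1", region = regions, volume_mm3 = vols,
                     test = 0.9, retest = 0.88)
  obs0 <- rbind(obs0, transform(obs0, subject = "s2"))
  expect_equal(volume_trt_correlation(obs0)$r_squared, 0, tolerance = 1e-12)

  # contracts
  expect_error(volume_trt_correlation(obs[obs$region %in% c("r1", "r2"), ]),
               "3 regions")
  obsc <- transform(obs, volume_mm3 = 1000)
  expect_error(volume_trt_correlation(obsc), "constant")
})

test_that("mixed-effects agreement: identity data gives slope 1 with marginal R^2 1", {
  obs <- make_obs(rep(seq(0.8, 1.0, length.out = 10), 3),
                  rep(seq(0.8, 1.0, length.out = 10), 3),
                  paste0("s", 1:3), paste0("r", 1:10))
  obs$amyloid_status <- NULL
  expect_message(res <- lme_test_retest(obs), "degenerate")
  expect_equal(res$slope, 1, tolerance = 1e-9)
  expect_equal(res$marginal_r2, 1)
  expect_equal(unname(diff(res$ci95)), 0)
})

test_that("mixed-effects CI covers a known generating slope across replicates", {
  n_sub <- 12
  n_reg <- 22
  slope <- 0.9
  set.seed(314)
  covered <- logical(100)
  for (k in seq_len(100)) {
    tv <- rep(seq(0.75, 1.05, length.out = n_reg), n_sub) +
      rnorm(n_sub * n_reg, sd = 0.02)
    b <- rep(rnorm(n_sub, sd = 0.01), each = n_reg)
    rv <- slope * tv + b + rnorm(n_sub * n_reg, sd = 0.005)
    obs <- data.frame(subject = rep(paste0("s", 1:n_sub), each = n_reg),
                      region = rep(paste0("r", 1:n_reg), n_sub),
                      volume_mm3 = 1000, test = tv, retest = rv)
    res <- lme_test_retest(obs)
    covered[k] <- res$ci95[1] <= slope && slope <= res$ci95[2]
  }
  expect_gte(mean(covered), 0.9)
})

test_that("a constant amyloid covariate is dropped without changing the slope", {
  set.seed(77)
  tv <- runif(30, 0.8, 1.0)
  rv <- tv + rnorm(30, sd = 0.01)
  base <- data.frame(subject = rep(paste0("s", 1:3), each = 10),
                     region = rep(paste0("r", 1:10), 3),
                     volume_mm3 = 1000, test = tv, retest = rv)
  plain <- lme_test_retest(base)
  withcov <- base
  withcov$amyloid_status <- "negative"
  expect_warning(res <- lme_test_retest(withcov), "constant")
  expect_equal(res$slope, plain$slope, tolerance = 1e-9)
  # single subject: random intercept not identifiable
  one <- base[base$subject == "s1", ]
  expect_error(lme_test_retest(one), "OLS")
})

test_that("Bland-Altman: hand-computed bias/SD and exact limits of agreement", {
  # identical pairs
  ba0 <- bland_altman(test = c(0.9, 0.8), retest = c(0.9, 0.8))
  expect_equal(ba0$bias_pct, 0)
  expect_equal(ba0$sd_pct, 0)
  # pairs (1.0, 0.9) and (0.9, 1.0): signed differences +/- 200/19 %
  ba <- bland_altman(test = c(1.0, 0.9), retest = c(0.9, 1.0))
  d <- 100 * 0.1 / 0.95
  expect_equal(ba$bias_pct, 0)
  expect_equal(ba$sd_pct, sqrt(2) * d)  # sample SD of (+d, -d)
  # LoA identity holds exactly
  set.seed(8)
  tv <- runif(20, 0.7, 1.1)
  rv <- tv * (1 + rnorm(20, sd = 0.03))
  ba2 <- bland_altman(test = tv, retest = rv)
  expect_identical(unname(ba2$loa),
                   c(ba2$bias_pct - 1.96 * ba2$sd_pct,
                     ba2$bias_pct + 1.96 * ba2$sd_pct))
  # swapping test and retest negates the bias, SD unchanged
  ba3 <- bland_altman(test = rv, retest = tv)
  expect_equal(ba3$bias_pct, -ba2$bias_pct)
  expect_equal(ba3$sd_pct, ba2$sd_pct)
  # |bias| is bounded by the mean absolute percent difference
  expect_lte(abs(ba2$bias_pct), mean(trt_variability(tv, rv)))
  expect_error(bland_altman(test = 1, retest = 1), "2 pairs")
  expect_error(bland_altman(test = c(1, 1), retest = c(-1, 1)), "non-zero")
})

test_that("Mann-Whitney exact p matches hand enumeration and the permutation oracle", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")

  tied <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(tied$p_value, 1)

  set.seed(21)
  for (k in 1:8) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    a <- sample(1:6, n1, replace = TRUE)  # replace=TRUE forces ties
    b <- sample(1:6, n2, replace = TRUE)
    got <- mann_whitney_u(a, b)
    expect_equal(got$p_value, oracle_mwu_p(a, b),
                 info = paste("a:", paste(a, collapse = ","),
                              "b:", paste(b, collapse = ",")))
  }
  # CU/AD group sizes (5, 6) take the exact path
  expect_equal(mann_whitney_u(rnorm(5), rnorm(6))$method, "exact")
  # large samples switch to the normal approximation
  set.seed(1)
  big <- mann_whitney_u(rnorm(15, 1), rnorm(15))
  expect_equal(big$method, "normal")
  expect_lt(big$p_value, 0.05)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})
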