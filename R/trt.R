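# Test-retest precision statistics: percent TRT variability, volume trend,
# mixed-effects agreement, Bland-Altman, exact Mann-Whitney group comparison.

#' Percent test-retest variability
#'
#' `TRT% = |T - R| / (0.5 * |T + R|) * 100`: the absolute test-retest
#' difference as a percentage of the pair mean. Vectorised over pairs.
#'
#' @param test,retest Numeric vectors of paired parameter estimates.
#' @return Percent TRT variability per pair (always >= 0).
#' @examples
#' trt_variability(0.93, 0.91)  # 2.174 %
#' @export
trt_variability <- function(test, retest) {
  if (length(test) != length(retest))
    stop("'test' and 'retest' must have equal length")
  s <- test + retest
  if (any(!is.finite(s)) || any(s == 0))
    stop("T + R must be finite and non-zero for every pair")
  abs(test - retest) / (0.5 * abs(s)) * 100
}

# validate a paired regional observations table
.check_obs <- function(obs, need = c("subject", "region", "volume_mm3",
                                     "test", "retest")) {
  if (!is.data.frame(obs) || nrow(obs) == 0)
    stop("'obs' must be a non-empty data.frame")
  missing <- setdiff(need, names(obs))
  if (length(missing))
    stop("'obs' lacks columns: ", paste(missing, collapse = ", "))
  if (any(duplicated(obs[c("subject", "region")])))
    stop("'obs' must have one row per (subject, region)")
  if (any(obs$test <= 0) || any(obs$retest <= 0))
    stop("test and retest values must be > 0")
  obs
}

#' Per-region mean test-retest variability table
#'
#' Applies the percent TRT formula per subject and region, then averages
#' across subjects within each region (unweighted). The global composite row
#' is computed from each subject's volume-weighted composite test and retest
#' values — not by averaging the regional TRT means.
#'
#' @param obs Data.frame with one row per (subject, region): columns
#'   `subject`, `region`, `volume_mm3`, `test`, `retest`.
#' @return Data.frame with columns `region`, `n_subjects`,
#'   `mean_volume_mm3`, `mean_trt_pct`; the composite row comes first.
#' @export
regional_trt_table <- function(obs) {
  obs <- .check_obs(obs)
  obs$trt <- trt_variability(obs$test, obs$retest)
  regions <- unique(obs$region)
  reg <- do.call(rbind, lapply(regions, function(rg) {
    d <- obs[obs$region == rg, ]
    data.frame(region = rg, n_subjects = nrow(d),
               mean_volume_mm3 = mean(d$volume_mm3),
               mean_trt_pct = mean(d$trt))
  }))
  subjects <- unique(obs$subject)
  comp_trt <- vapply(subjects, function(s) {
    d <- obs[obs$subject == s, ]
    Tc <- sum(d$volume_mm3 * d$test) / sum(d$volume_mm3)
    Rc <- sum(d$volume_mm3 * d$retest) / sum(d$volume_mm3)
    trt_variability(Tc, Rc)
  }, numeric(1))
  out <- rbind(data.frame(region = composite_region_name(),
                          n_subjects = length(subjects),
                          mean_volume_mm3 = mean(tapply(obs$volume_mm3,
                                                        obs$subject, sum)),
                          mean_trt_pct = mean(comp_trt)),
               reg)
  rownames(out) <- NULL
  out
}

#' Relationship between regional size and TRT variability
#'
#' Ordinary least-squares regression of per-region mean TRT% on per-region
#' volume, quantifying the expectation that larger regions show smaller
#' test-retest variability.
#'
#' @inheritParams regional_trt_table
#' @return List with `r_squared`, `p_value` (two-sided, slope), `slope`,
#'   `n_regions`.
#' @export
volume_trt_correlation <- function(obs) {
  obs <- .check_obs(obs)
  tab <- regional_trt_table(obs)
  tab <- tab[tab$region != composite_region_name(), ]
  if (nrow(tab) < 3) stop("need at least 3 regions")
  if (stats::sd(tab$mean_volume_mm3) == 0)
    stop("regional volumes are constant; correlation undefined")
  if (stats::sd(tab$mean_trt_pct) == 0)
    return(list(r_squared = 0, p_value = 1, slope = 0,
                n_regions = nrow(tab)))
  fit <- stats::lm(mean_trt_pct ~ mean_volume_mm3, data = tab)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients["mean_volume_mm3", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)["mean_volume_mm3"]),
       n_regions = nrow(tab))
}

#' Mixed-effects agreement between test and retest
#'
#' Regresses retest on test with a random intercept per subject (accounting
#' for the within-subject correlation between regions) and, when it varies,
#' amyloid status as a fixed covariate. Reports the test slope, its 95%
#' confidence interval, and the marginal (fixed-effects) R-squared
#' `var(Xb) / (var(Xb) + var(intercept) + var(residual))`.
#'
#' If the retest values are numerically identical to a linear function of
#' the test values (zero residual variance, as in a noise-free phantom), the
#' mixed model is degenerate and the exact least-squares answer is returned
#' with a zero-width interval and a message.
#'
#' @param obs Data.frame with columns `subject`, `region`, `test`,
#'   `retest` and optionally `amyloid_status`.
#' @return List with `slope`, `ci95`, `marginal_r2`, `p_value` (slope != 0),
#'   `covariate_used`, and the fitted `model` (NULL on the degenerate path).
#' @export
lme_test_retest <- function(obs) {
  obs <- .check_obs(obs, need = c("subject", "region", "test", "retest"))
  if (length(unique(obs$subject)) < 2)
    stop("only one subject: a random intercept is not identifiable; ",
         "fit plain OLS instead")
  if (length(unique(obs$region)) < 2)
    stop("need at least 2 regions")
  use_cov <- "amyloid_status" %in% names(obs) &&
    length(unique(obs$amyloid_status)) > 1
  if ("amyloid_status" %in% names(obs) && !use_cov)
    warning("amyloid_status is constant; covariate dropped")
  ols <- stats::lm(retest ~ test, data = obs)
  if (stats::sd(stats::residuals(ols)) <
      1e-9 * max(stats::sd(obs$retest), 1e-12)) {
    message("retest is an exact linear function of test; ",
            "returning the degenerate least-squares solution")
    sl <- unname(stats::coef(ols)["test"])
    return(list(slope = sl, ci95 = c(sl, sl), marginal_r2 = 1,
                p_value = 0, covariate_used = FALSE, model = NULL))
  }
  fml <- if (use_cov) retest ~ test + amyloid_status else retest ~ test
  fit <- nlme::lme(fixed = fml, random = ~ 1 | subject, data = obs,
                   method = "REML")
  tt <- summary(fit)$tTable
  est <- tt["test", "Value"]
  se <- tt["test", "Std.Error"]
  dfr <- tt["test", "DF"]
  ci <- est + c(-1, 1) * stats::qt(0.975, dfr) * se
  fixed_fit <- as.numeric(stats::predict(fit, level = 0))
  var_f <- stats::var(fixed_fit)
  vc <- nlme::VarCorr(fit)
  var_re <- as.numeric(vc["(Intercept)", "Variance"])
  var_e <- fit$sigma^2
  list(slope = unname(est), ci95 = ci,
       marginal_r2 = var_f / (var_f + var_re + var_e),
       p_value = unname(tt["test", "p-value"]),
       covariate_used = use_cov, model = fit)
}

#' Bland-Altman analysis in percent of the pair mean
#'
#' Signed per-pair percent difference `d = 100 * (T - R) / (0.5 * (T + R))`;
#' bias is the mean of `d`, spread its sample SD, and the limits of
#' agreement are `bias +/- 1.96 * SD` exactly.
#'
#' @param obs Data.frame with columns `test` and `retest` (>= 2 rows), or
#'   two numeric vectors via `test`/`retest`.
#' @param test,retest Optional numeric vectors used when `obs` is missing.
#' @return Object of class `bland_altman`: `bias_pct`, `sd_pct`, `loa`
#'   (lower, upper), `diffs_pct`, `means`.
#' @export
bland_altman <- function(obs = NULL, test = NULL, retest = NULL) {
  if (!is.null(obs)) {
    test <- obs$test
    retest <- obs$retest
  }
  if (length(test) < 2) stop("need at least 2 pairs")
  s <- test + retest
  if (any(!is.finite(s)) || any(s == 0))
    stop("T + R must be finite and non-zero for every pair")
  d <- 100 * (test - retest) / (0.5 * s)
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias_pct = bias, sd_pct = sdd,
                 loa = c(lower = bias - 1.96 * sdd,
                         upper = bias + 1.96 * sdd),
                 diffs_pct = d, means = 0.5 * s),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat(sprintf("Bland-Altman: bias %.*f %% (SD %.*f %%), LoA [%.*f, %.*f] %%, n = %d\n",
              digits, x$bias_pct, digits, x$sd_pct,
              digits, x$loa[["lower"]], digits, x$loa[["upper"]],
              length(x$diffs_pct)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ..., xlab = "Pair mean",
                              ylab = "Difference (% of pair mean)") {
  graphics::plot(x$means, x$diffs_pct, pch = 16, xlab = xlab, ylab = ylab,
                 ylim = range(c(x$diffs_pct, x$loa)) * 1.1,
                 main = "Bland-Altman", ...)
  graphics::abline(h = x$bias_pct, col = "firebrick", lwd = 2)
  graphics::abline(h = x$loa, col = "firebrick", lty = 2)
  invisible(x)
}

#' Mann-Whitney U test with exact tie-aware enumeration
#'
#' The U statistic is computed from mid-ranks. For combined sample sizes up
#' to `exact_limit` the two-sided p-value is exact: every assignment of the
#' pooled observations to the two groups is enumerated and
#' `p = min(1, 2 * min(P(U <= u), P(U >= u)))` under that permutation null
#' (ties handled by mid-ranks throughout). Above the limit a normal
#' approximation with tie correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_limit Combined-n cutoff for exact enumeration (default 20).
#' @return List with `U` (for group `a`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_limit = 20) {
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)  # mid-ranks for ties
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_limit) {
    combos <- utils::combn(n, n1)
    Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p_value = p, method = method)
}
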