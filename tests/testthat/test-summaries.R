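# build a converged tto_fit directly from known parameter values
fit_from <- function(spec, sample, method = "tbe") {
  structure(list(spec = spec, method = method, family = spec$family,
                 loglik = 0, converged = TRUE, n_used = sample$n,
                 diagnostics = list(), sample = sample),
            class = "tto_fit")
}

test_that("the observable probability is the fitted CDF at t* and is monotone", {
  s <- truncated_sample(c(10, 200), c(520, 529))
  f <- fit_from(tto_family("weibull", 0.00468, 1.49), s)
  expect_equal(estimate_p(f, 529), ptto(529, f$spec))
  ps <- vapply(c(100, 300, 529, 2000), function(ts) estimate_p(f, ts),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_equal(estimate_p(f, 1e9), 1, tolerance = 1e-12)

  bad <- f
  bad$converged <- FALSE
  expect_error(estimate_p(bad, 529), "converge")
  expect_error(expected_tto(bad), "converge")
})

test_that("expected time-to-onset delegates to the family mean", {
  s <- truncated_sample(c(10, 200), c(520, 529))
  f <- fit_from(tto_family("weibull", 0.00468, 1.49), s)
  expect_equal(expected_tto(f), gamma(1 + 1 / 1.49) / 0.00468)
  fh <- fit_from(tto_family("loglogistic", 0.01, 0.8), s)
  expect_warning(m <- expected_tto(fh), class = "tto_undefined_mean")
  expect_true(is.na(m))
})

test_that("ignoring truncation shortens the estimated expected onset time", {
  # the two Weibull fits reported for the lymphoma application
  s <- truncated_sample(c(10, 200), c(520, 529))
  naive <- fit_from(tto_family("weibull", 0.00666, 1.55), s, "naive")
  tbe <- fit_from(tto_family("weibull", 0.00468, 1.49), s, "tbe")
  expect_lt(expected_tto(naive), expected_tto(tbe))
})

test_that("BCa machinery: percentile reduction, level ordering, degeneracy", {
  stats_b <- seq(1, 100, by = 1)
  point <- 50.5  # median of the draws: z0 = 0; pass a = 0 explicitly
  bca <- ttonset:::.bca_interval(stats_b, point, 0.95, a = 0)
  expect_equal(bca$z0, 0)
  expect_equal(c(bca$lower, bca$upper),
               unname(quantile(stats_b, c(0.025, 0.975), type = 7)))
  expect_equal(bca$percentile,
               unname(quantile(stats_b, c(0.025, 0.975), type = 7)))

  wide <- ttonset:::.bca_interval(stats_b, point, 0.95, a = 0)
  narrow <- ttonset:::.bca_interval(stats_b, point, 0.80, a = 0)
  expect_lt(wide$lower, narrow$lower)
  expect_gt(wide$upper, narrow$upper)

  flat <- ttonset:::.bca_interval(rep(7, 50), 7, 0.95, a = 0)
  expect_identical(c(flat$lower, flat$upper), c(7, 7))
})

test_that("bootstrap intervals resample pairs, refit and keep accounts", {
  scn <- tto_scenario("exponential", 0.05, p = 0.8, n = 80, seed = 44)
  s <- draw_truncated_sample(scn, seed = 44)
  ci <- bootstrap_ci(s, "exponential", "tbe", "mean", n_boot = 200,
                     level = 0.95, seed = 7)
  expect_s3_class(ci, "tto_boot")
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)
  expect_equal(ci$n_boot, 200L)
  expect_false(ci$unreliable)
  expect_output(print(ci), "BCa")

  # identical seed, identical interval
  ci2 <- bootstrap_ci(s, "exponential", "tbe", "mean", n_boot = 200,
                      level = 0.95, seed = 7)
  expect_identical(c(ci$lower, ci$upper), c(ci2$lower, ci2$upper))

  # a degenerate statistic: F(huge t*) is 1 on every resample
  cd <- bootstrap_ci(s, "exponential", "tbe", "p_hat", n_boot = 100,
                     seed = 8, t_star = 1e9)
  expect_identical(c(cd$lower, cd$upper), c(1, 1))

  expect_error(bootstrap_ci(s, "exponential", statistic = "beta",
                            n_boot = 100, seed = 1), "beta")
  expect_error(bootstrap_ci(s, "exponential", n_boot = 10), "at least 100")
})

test_that("an undefined statistic at the point estimate refuses an interval", {
  # heavy-tailed log-logistic: fitted shape stays below 1, mean undefined
  scn <- tto_scenario("loglogistic", 0.05, 0.5, p = 0.8, n = 150, seed = 51)
  s <- draw_truncated_sample(scn, seed = 51)
  f <- fit_tto(s, "loglogistic", "tbe")
  expect_true(f$converged)
  expect_lt(coef(f)[["beta"]], 1)
  expect_error(
    bootstrap_ci(s, "loglogistic", "tbe", "mean", n_boot = 100, seed = 1),
    "undefined")
})

test_that("our BCa interval agrees with the boot package on a smooth statistic", {
  skip_if_not_installed("boot")
  scn <- tto_scenario("exponential", 0.05, p = 0.8, n = 100, seed = 61)
  s <- draw_truncated_sample(scn, seed = 61)
  ours <- bootstrap_ci(s, "exponential", "naive", "lambda", n_boot = 2000,
                       seed = 3)
  bt <- boot::boot(seq_len(s$n), function(d, i) {
    length(i) / sum(s$x[i])
  }, R = 2000)
  bci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  # independent resampling streams: agree within a few bootstrap SEs
  tol <- 4 * sd(bt$t) / sqrt(10)
  expect_lt(abs(ours$lower - bci[1]), tol)
  expect_lt(abs(ours$upper - bci[2]), tol)
})

test_that("the application report lines up fits, p-hat and expectations", {
  scn <- tto_scenario("weibull", 0.005, 1.5, p = 0.9, n = 80, seed = 71)
  s <- draw_truncated_sample(scn, seed = 71)
  rep_tab <- application_report(s, families = c("exponential", "weibull"),
                                n_boot = 0)
  expect_equal(nrow(rep_tab), 2)
  expect_true(all(rep_tab$tbe_converged))
  w <- rep_tab[rep_tab$family == "weibull", ]
  expect_equal(w$p_hat,
               ptto(max(s$t), tto_family("weibull", w$tbe_lambda,
                                         w$tbe_beta)))
  # naive rates exceed TBE rates under truncation
  expect_gt(w$naive_lambda, w$tbe_lambda)
})
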