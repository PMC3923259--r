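test_that("scenario construction derives tau from p and validates inputs", {
  scn <- tto_scenario("exponential", 0.05, p = 0.25, n = 100, seed = 1)
  expect_equal(scn$tau, qtto(0.25, scn$spec))
  expect_equal(ptto(scn$tau, scn$spec), 0.25)
  expect_error(tto_scenario("exponential", 0.05, p = 0, n = 10), "p")
  expect_error(tto_scenario("exponential", 0.05, p = 0.5, n = 0), "n")
  expect_error(tto_scenario("exponential", 0.05, p = 0.5, n = 10,
                            n_reps = 0), "n_reps")
})

test_that("accepted pairs respect the truncation design exactly", {
  scn <- tto_scenario("weibull", 0.05, 0.5, p = 0.5, n = 300, seed = 2)
  s <- draw_truncated_sample(scn, seed = 2)
  expect_equal(s$n, 300)
  expect_true(all(s$x <= s$t))
  expect_lte(max(s$t), scn$tau)
  expect_lte(max(s$x), scn$tau)
})

test_that("the empirical acceptance rate matches the closed-form integral", {
  # P(X <= T) with T ~ U(0, tau) is (1/tau) * int_0^tau F(u) du
  scn <- tto_scenario("exponential", 0.05, p = 0.8, n = 4000, seed = 3)
  lam <- 0.05
  tau <- scn$tau
  p_acc <- (tau - (1 - exp(-lam * tau)) / lam) / tau
  s <- draw_truncated_sample(scn, seed = 3)
  total <- attr(s, "draws_total")
  se <- sqrt(p_acc * (1 - p_acc) / total)
  expect_lt(abs(attr(s, "acceptance_rate") - p_acc), 3 * se)
})

test_that("accepted onsets follow the length-biased conditional law", {
  scn <- tto_scenario("weibull", 0.05, 2, p = 0.5, n = 2000, seed = 4)
  s <- draw_truncated_sample(scn, seed = 4)
  # density of accepted X: f(u) * (1 - u/tau) on (0, tau), renormalized
  spec <- scn$spec
  tau <- scn$tau
  norm <- integrate(function(u) dtto(u, spec) * (1 - u / tau), 0, tau,
                    rel.tol = 1e-10)$value
  cdf_acc <- function(q) {
    vapply(q, function(qi) {
      integrate(function(u) dtto(u, spec) * (1 - u / tau), 0, qi,
                rel.tol = 1e-10)$value / norm
    }, numeric(1))
  }
  ks <- suppressWarnings(ks.test(s$x, cdf_acc))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling and summaries are bit-identical under a fixed seed", {
  scn <- tto_scenario("loglogistic", 1, 2, p = 0.5, n = 60, n_reps = 5,
                      seed = 9)
  s1 <- draw_truncated_sample(scn, seed = 99)
  s2 <- draw_truncated_sample(scn, seed = 99)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$t, s2$t)
  r1 <- run_scenario(scn)
  r2 <- run_scenario(scn)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$estimates, r2$estimates)
})

test_that("a one-replication summary is that replication's signed error", {
  scn <- tto_scenario("exponential", 0.05, p = 0.8, n = 50, n_reps = 1,
                      seed = 12)
  rs <- run_scenario(scn)
  s <- draw_truncated_sample(scn, seed = ttonset:::.mix_seed(scn$seed, 1))
  lam_hat <- unname(coef(fit_tto(s, "exponential", "naive")))
  row <- rs$table[rs$table$method == "naive", ]
  expect_equal(row$bias, lam_hat - 0.05)
  expect_equal(row$mse, (lam_hat - 0.05)^2)
  expect_equal(row$prop_above, as.numeric(lam_hat > 0.05))
  expect_true(all(rs$table$mse >= rs$table$bias^2 - 1e-12))
})

test_that("the default scenario grid is the full 60-scenario study design", {
  grid <- scenario_grid()
  expect_length(grid, 60)
  fams <- vapply(grid, function(s) s$spec$family, character(1))
  expect_equal(sum(fams == "exponential"), 12)
  expect_equal(sum(fams == "weibull"), 24)
  expect_equal(sum(fams == "loglogistic"), 24)
  expect_true(all(vapply(grid, function(s) s$n_reps, integer(1)) == 1000L))

  one <- scenario_grid(list(families = "exponential", lambda = 0.05,
                            p = 0.5, n = 100))
  expect_length(one, 1)

  g1 <- scenario_grid(list(seed = 77))
  g2 <- scenario_grid(list(seed = 77))
  expect_identical(vapply(g1, function(s) s$seed, integer(1)),
                   vapply(g2, function(s) s$seed, integer(1)))
  expect_error(scenario_grid(list(p = numeric(0))), "empty")
})

test_that("scenario configs round-trip through YAML and JSON files", {
  cfg <- list(families = "exponential", lambda = 0.05, p = c(0.25, 0.8),
              n = 50, n_reps = 2, seed = 5)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  expect_length(scenario_grid(yml), 2)
  expect_length(scenario_grid(jsn), 2)
})

test_that("naive bias grows as the observable window shrinks", {
  biases <- vapply(c(0.25, 0.5, 0.8), function(p) {
    scn <- tto_scenario("exponential", 0.05, p = p, n = 100,
                        n_reps = 150, seed = 81)
    rs <- run_scenario(scn, methods = "naive")
    rs$table$bias
  }, numeric(1))
  expect_true(all(diff(biases) < 0))  # p = 0.25 worst, p = 0.8 best
})

test_that("run_grid tabulates scenario conditions next to the summaries", {
  grid <- scenario_grid(list(families = "exponential", lambda = 0.05,
                             p = c(0.5, 0.8), n = 40, n_reps = 3,
                             seed = 6))
  tab <- run_grid(grid)
  expect_equal(nrow(tab), 4)  # 2 scenarios x 2 methods x 1 parameter
  expect_true(all(c("family", "lambda", "beta", "p", "n", "method",
                    "bias", "mse", "prop_above", "npm") %in% names(tab)))
  csv <- tempfile(fileext = ".csv")
  write_scenario_summary(tab, csv)
  back <- read.csv(csv)
  expect_equal(back$bias, tab$bias)
})
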