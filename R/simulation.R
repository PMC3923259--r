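# deterministic seed mixing: keeps derived seeds inside 32-bit range
.mix_seed <- function(a, b) {
  as.integer((((as.numeric(a) %% 94906249) * 22695477 +
                 as.numeric(b) * 7919 + 12345) %% 2147483629))
}

#' Define a truncated-sampling simulation scenario
#'
#' A scenario fixes the data-generating conditions of the Monte-Carlo
#' study: the true time-to-onset family and parameters, the probability
#' `p` that an onset falls in the observable window, the accepted sample
#' size `n`, the replication count and a seed. The truncation-time upper
#' bound is always derived as `tau = qtto(p, spec)` (so `P(X < tau) = p`),
#' never user-supplied; truncation times are uniform on `[0, tau]` and
#' `1 - p` lower-bounds the truncated fraction `P(X > T)`.
#'
#' @inheritParams tto_family
#' @param p Observable probability, in (0, 1).
#' @param n Accepted sample size per replication.
#' @param n_reps Number of replications.
#' @param seed Integer seed for the scenario substream.
#' @return An object of class `"tto_scenario"`.
#' @export
tto_scenario <- function(family, lambda, beta = NULL, p, n,
                         n_reps = 1000L, seed = 1L) {
  spec <- tto_family(family, lambda = lambda, beta = beta)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- as.integer(n)
  n_reps <- as.integer(n_reps)
  if (is.na(n) || n < 1L) stop("`n` must be a positive count", call. = FALSE)
  if (is.na(n_reps) || n_reps < 1L) {
    stop("`n_reps` must be a positive count", call. = FALSE)
  }
  structure(list(spec = spec, p = p, n = n, n_reps = n_reps,
                 seed = as.integer(seed), tau = qtto(p, spec)),
            class = "tto_scenario")
}

#' @export
print.tto_scenario <- function(x, ...) {
  th <- .theta(x$spec)
  cat("<tto_scenario> ", x$spec$family, " (",
      paste(names(th), "=", format(th), collapse = ", "),
      "), p = ", x$p, " (tau = ", signif(x$tau, 4), "), n = ", x$n,
      ", ", x$n_reps, " replication(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Draw exactly n accepted (x, t) pairs: X from `spec`, T ~ U(0, tau),
# independent; a pair is kept iff x <= t, otherwise both coordinates are
# redrawn. Batched drawing is distributionally identical to one-at-a-time
# redrawing and keeps the loop in vectorized code.
.draw_pairs <- function(spec, tau, n, max_draws = 1e7) {
  xs <- numeric(0)
  ts <- numeric(0)
  total <- 0
  accepted <- 0
  rate <- NA_real_
  while (length(xs) < n) {
    need <- n - length(xs)
    m <- if (is.na(rate)) max(512L, 4L * need)
         else ceiling(need / max(rate, 0.005)) + 64L
    m <- min(m, 2e6)
    x <- qtto(stats::runif(m), spec)
    t <- tau * stats::runif(m)
    keep <- x <= t
    total <- total + m
    accepted <- accepted + sum(keep)
    rate <- accepted / total
    if (total > max_draws) {
      stop("rejection sampling exceeded ", format(max_draws, scientific = FALSE),
           " draws (acceptance rate ~", signif(rate, 3),
           "); the scenario's p and parameters make acceptance too rare",
           call. = FALSE)
    }
    xs <- c(xs, x[keep])
    ts <- c(ts, t[keep])
  }
  out <- truncated_sample(xs[seq_len(n)], ts[seq_len(n)], unit = "time")
  attr(out, "draws_total") <- total
  attr(out, "acceptance_rate") <- rate
  out
}

#' Draw one right-truncated sample under a scenario
#'
#' Generates independent pairs `(X, T)` with `X` from the scenario's
#' family and `T` uniform on `[0, tau]`, keeping a pair only when
#' `x <= t` (the case would have been reported) and fully redrawing both
#' coordinates otherwise, until exactly `n` pairs are accepted. Every
#' returned time satisfies `x_i <= t_i <= tau`, hence also `x_i <= tau`.
#' A guard aborts if more than `1e7` total draws are needed.
#'
#' @param scenario A [tto_scenario()].
#' @param seed Optional integer seed (set before drawing); when `NULL`
#'   the current RNG stream is used.
#' @return A [truncated_sample()] of size `scenario$n`.
#' @export
draw_truncated_sample <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "tto_scenario"))
  if (!is.null(seed)) set.seed(seed)
  .draw_pairs(scenario$spec, scenario$tau, scenario$n)
}

#' Run the replication study for one scenario
#'
#' For each replication: draws a right-truncated sample (per-replication
#' seed derived from the scenario seed, so any replication can be
#' regenerated independently), fits the requested likelihoods on the true
#' family, and records estimates and convergence. Summaries — per-parameter
#' bias `mean(theta_hat - theta)`, mean squared error
#' `mean((theta_hat - theta)^2)` and over-estimation proportion
#' `mean(theta_hat > theta)` — are computed per method over the
#' replications where that method's maximization succeeded; the excluded
#' count is reported as `npm` ("problem of maximization"). Note that which
#' replications count as failures depends on the optimizer's convergence
#' and boundary rules (see [tto_control()]), so `npm` is a diagnostic, not
#' a reproducible constant.
#'
#' @param scenario A [tto_scenario()].
#' @param methods Estimation methods to run, subset of
#'   `c("naive", "tbe")`.
#' @param families_to_fit Families to fit; defaults to the scenario's true
#'   family. Extra families are fitted and their estimates returned, but
#'   bias/MSE rows are only meaningful (and only produced) for the true
#'   family.
#' @param control A [tto_control()].
#' @return An object of class `"tto_scenario_summary"`: list with
#'   `scenario`, `table` (one row per method and parameter: `bias`, `mse`,
#'   `prop_above`, `n_used`, `npm`), and `estimates` / `converged`
#'   (per-family matrices of replication-level results).
#' @examples
#' scn <- tto_scenario("exponential", lambda = 0.05, p = 0.8, n = 50,
#'                     n_reps = 20, seed = 3)
#' run_scenario(scn)$table
#' @export
run_scenario <- function(scenario, methods = c("naive", "tbe"),
                         families_to_fit = NULL,
                         control = tto_control()) {
  stopifnot(inherits(scenario, "tto_scenario"))
  methods <- match.arg(methods, c("naive", "tbe"), several.ok = TRUE)
  true_family <- scenario$spec$family
  if (is.null(families_to_fit)) families_to_fit <- true_family
  true_theta <- .theta(scenario$spec)
  R <- scenario$n_reps

  estimates <- list()
  converged <- list()
  for (fam in families_to_fit) {
    npar <- if (fam == "exponential") 1L else 2L
    for (m in methods) {
      key <- paste(fam, m, sep = "_")
      estimates[[key]] <- matrix(NA_real_, R, npar,
        dimnames = list(NULL, c("lambda", "beta")[seq_len(npar)]))
      converged[[key]] <- logical(R)
    }
  }

  for (r in seq_len(R)) {
    s <- draw_truncated_sample(scenario, seed = .mix_seed(scenario$seed, r))
    for (fam in families_to_fit) {
      naive_fit <- NULL
      for (m in methods) {
        key <- paste(fam, m, sep = "_")
        fit <- if (m == "tbe" && !is.null(naive_fit) && naive_fit$converged) {
          fit_tto(s, fam, "tbe", init = naive_fit$spec, control = control)
        } else {
          fit_tto(s, fam, m, control = control)
        }
        if (m == "naive") naive_fit <- fit
        estimates[[key]][r, ] <- unname(.theta(fit$spec))
        converged[[key]][r] <- fit$converged
      }
    }
  }

  rows <- list()
  for (m in methods) {
    key <- paste(true_family, m, sep = "_")
    est <- estimates[[key]]
    ok <- converged[[key]]
    npm <- sum(!ok)
    for (j in seq_along(true_theta)) {
      e <- est[ok, j]
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, parameter = names(true_theta)[j],
        true = unname(true_theta[j]),
        bias = if (length(e)) mean(e - true_theta[j]) else NA_real_,
        mse = if (length(e)) mean((e - true_theta[j])^2) else NA_real_,
        prop_above = if (length(e)) mean(e > true_theta[j]) else NA_real_,
        n_used = length(e), npm = npm)
    }
  }
  structure(list(scenario = scenario,
                 table = do.call(rbind, rows),
                 estimates = estimates, converged = converged),
            class = "tto_scenario_summary")
}

#' @export
print.tto_scenario_summary <- function(x, ...) {
  print(x$scenario)
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Build a grid of simulation scenarios
#'
#' Cartesian product of families, parameter values, observable
#' probabilities and sample sizes, with deterministic per-scenario seeds
#' derived from the master seed. The default configuration is the full
#' study grid: `lambda` in {0.05, 1}, shape `beta` in {0.5, 2} for the
#' two-parameter families, `p` in {0.25, 0.5, 0.8}, `n` in {100, 500} and
#' 1000 replications — 12 exponential scenarios plus 24 each for the
#' Weibull and log-logistic, 60 in total.
#'
#' @param config Optional list (or path to a YAML/JSON file) with any of
#'   the entries `families`, `lambda`, `beta`, `p`, `n`, `n_reps`,
#'   `seed`; missing entries take the defaults above.
#' @return A list of [tto_scenario()] objects.
#' @examples
#' length(scenario_grid())                 # 60
#' length(scenario_grid(list(families = "exponential", lambda = 0.05,
#'                           p = 0.5, n = 100)))  # 1
#' @export
scenario_grid <- function(config = NULL) {
  if (is.character(config)) config <- read_scenario_config(config)
  if (is.null(config)) config <- list()
  defaults <- list(families = c("exponential", "weibull", "loglogistic"),
                   lambda = c(0.05, 1), beta = c(0.5, 2),
                   p = c(0.25, 0.50, 0.80), n = c(100L, 500L),
                   n_reps = 1000L, seed = 1L)
  cfg <- utils::modifyList(defaults, config[names(config) != ""])
  for (dim in c("families", "lambda", "p", "n")) {
    if (length(cfg[[dim]]) == 0L) {
      stop("scenario grid dimension `", dim, "` is empty", call. = FALSE)
    }
  }
  out <- list()
  idx <- 0L
  for (fam in cfg$families) {
    betas <- if (fam == "exponential") list(NULL) else as.list(cfg$beta)
    if (fam != "exponential" && length(cfg$beta) == 0L) {
      stop("scenario grid dimension `beta` is empty", call. = FALSE)
    }
    for (lam in cfg$lambda) for (bet in betas) {
      for (p in cfg$p) for (n in cfg$n) {
        idx <- idx + 1L
        out[[idx]] <- tto_scenario(fam, lambda = lam, beta = bet, p = p,
                                   n = n, n_reps = cfg$n_reps,
                                   seed = .mix_seed(cfg$seed, idx))
      }
    }
  }
  out
}

#' @rdname scenario_grid
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run a list of scenarios and tabulate the results
#'
#' Applies [run_scenario()] to each scenario and binds the per-scenario
#' summary tables into one data frame with the scenario conditions as
#' leading columns (one row per scenario, method and parameter:
#' bias, MSE, over-estimation proportion, effective replication count and
#' failed-maximization count).
#'
#' @param scenarios List of [tto_scenario()] (e.g. from
#'   [scenario_grid()]).
#' @param methods Passed to [run_scenario()].
#' @param control Passed to [run_scenario()].
#' @param verbose Emit one progress message per scenario.
#' @return A data frame; write it with [write_scenario_summary()].
#' @export
run_grid <- function(scenarios, methods = c("naive", "tbe"),
                     control = tto_control(), verbose = FALSE) {
  out <- lapply(seq_along(scenarios), function(i) {
    scn <- scenarios[[i]]
    if (verbose) {
      th <- .theta(scn$spec)
      message("scenario ", i, "/", length(scenarios), ": ",
              scn$spec$family, " (",
              paste(names(th), "=", format(th), collapse = ", "),
              "), p = ", scn$p, ", n = ", scn$n, ", seed = ", scn$seed)
    }
    res <- run_scenario(scn, methods = methods, control = control)
    th <- .theta(scn$spec)
    cbind(data.frame(family = scn$spec$family, lambda = th[["lambda"]],
                     beta = if ("beta" %in% names(th)) th[["beta"]]
                            else NA_real_,
                     p = scn$p, n = scn$n, n_reps = scn$n_reps,
                     seed = scn$seed),
          res$table, row.names = NULL)
  })
  do.call(rbind, out)
}

#' @rdname run_grid
#' @param summary_table Data frame returned by [run_grid()].
#' @param path Output CSV path.
#' @export
write_scenario_summary <- function(summary_table, path) {
  utils::write.csv(summary_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
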