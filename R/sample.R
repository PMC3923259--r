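#' Right-truncated case sample
#'
#' Bundles paired observations from a spontaneous reporting database:
#' `x[i]` is the time-to-onset (lag from treatment initiation to the
#' adverse reaction) and `t[i]` the truncation time (lag from treatment
#' initiation to the time of analysis) of case `i`. A case can appear in
#' the database only if its reaction occurred before the analysis date, so
#' every pair must satisfy `x[i] <= t[i]`; this observability condition is
#' what makes the data right truncated rather than censored. Ties
#' `x[i] == t[i]` are valid observations.
#'
#' Times are durations in a single declared unit (the bundled examples use
#' weeks); calendar-date arithmetic is a pre-processing responsibility.
#'
#' @param x Numeric vector of times-to-onset, strictly positive.
#' @param t Numeric vector of truncation times, same length, with
#'   `x <= t` elementwise.
#' @param unit Free-text time unit label (default `"weeks"`).
#' @return An object of class `"tto_sample"` with elements `x`, `t`,
#'   `unit` and `n`.
#' @examples
#' s <- truncated_sample(x = c(12, 40, 210), t = c(100, 300, 520))
#' summary(s)
#' @export
truncated_sample <- function(x, t, unit = "weeks") {
  if (!is.numeric(x) || !is.numeric(t)) {
    stop("`x` and `t` must be numeric vectors", call. = FALSE)
  }
  if (length(x) != length(t)) {
    stop("`x` and `t` must have the same length", call. = FALSE)
  }
  if (length(x) < 1L) stop("at least one case is required", call. = FALSE)
  bad <- which(!is.finite(x) | !is.finite(t) | x <= 0 | t <= 0)
  if (length(bad)) {
    stop("all times must be strictly positive and finite; offending ",
         "case(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(x > t)
  if (length(bad)) {
    stop("the observability condition x <= t is violated for case(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (a reported case cannot have its onset after the analysis time)",
         call. = FALSE)
  }
  structure(list(x = as.numeric(x), t = as.numeric(t),
                 unit = as.character(unit)[1L], n = length(x)),
            class = "tto_sample")
}

#' @export
print.tto_sample <- function(x, ...) {
  cat("<tto_sample> ", x$n, " right-truncated cases (", x$unit, ")\n",
      sep = "")
  cat("  time-to-onset: [", format(min(x$x)), ", ", format(max(x$x)),
      "]   truncation time t*: ", format(max(x$t)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.tto_sample <- function(object, ...) {
  out <- rbind(time_to_onset = summary(object$x),
               truncation_time = summary(object$t))
  cat("Right-truncated sample, n = ", object$n, " (", object$unit, "), ",
      "t* = ", format(max(object$t)), "\n\n", sep = "")
  print(out)
  invisible(out)
}

#' @export
as.data.frame.tto_sample <- function(x, ...) {
  data.frame(time_to_onset = x$x, truncation_time = x$t)
}

#' Read and write case tables
#'
#' `read_cases()` reads a delimited case table (comma-separated, UTF-8,
#' `.` decimal) with header columns `time_to_onset` and `truncation_time`
#' (extra columns such as `case_id`, `drug`, `reaction` are carried along
#' but ignored for modelling) and validates it into a [truncated_sample()].
#' Rows violating positivity or the observability condition `x <= t` are
#' reported by row number — nothing is silently dropped. Cells that do not
#' parse as numbers (e.g. calendar dates) produce an error asking for
#' pre-computed lags.
#'
#' `write_cases()` writes a sample back in the same dialect.
#'
#' @param path File path.
#' @param unit Time unit label attached to the sample.
#' @param sample A [truncated_sample()].
#' @return `read_cases()`: a `tto_sample`; `write_cases()`: `path`,
#'   invisibly.
#' @export
read_cases <- function(path, unit = "weeks") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_to_onset", "truncation_time")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("column `", col, "` has non-numeric value(s) at row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "),
             " (e.g. \"", v[bad[1L]], "\"); times must be numeric lags ",
             "from treatment initiation, not dates — pre-compute lags",
             call. = FALSE)
      }
      df[[col]] <- vn
    }
  }
  x <- df$time_to_onset
  t <- df$truncation_time
  bad <- which(is.na(x) | is.na(t) | x <= 0 | t <= 0)
  if (length(bad)) {
    stop("row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         ": times must be strictly positive (rule: x > 0 and t > 0)",
         call. = FALSE)
  }
  bad <- which(x > t)
  if (length(bad)) {
    stop("row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         ": time_to_onset exceeds truncation_time (rule: x <= t; value ",
         format(x[bad[1L]]), " > ", format(t[bad[1L]]), ")", call. = FALSE)
  }
  truncated_sample(x, t, unit = unit)
}

#' @rdname read_cases
#' @export
write_cases <- function(sample, path) {
  stopifnot(inherits(sample, "tto_sample"))
  df <- as.data.frame(sample)
  # 17 significant digits: numeric values survive a write/read round trip
  df[] <- lapply(df, function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic case file
#'
#' Draws a right-truncated sample from a chosen family under the uniform
#' truncation-time design (see [draw_truncated_sample()]) and writes it as
#' a case table together with a JSON sidecar (`<path>.meta.json`)
#' recording the true parameters, the truncation bound `tau` and the seed,
#' so downstream checks can assert parameter recovery. Identical arguments
#' produce byte-identical files.
#'
#' @inheritParams tto_family
#' @param p Probability that the time-to-onset falls within the observable
#'   interval `[0, tau]`; `tau` is the `p`-quantile of the family.
#' @param n Number of accepted cases.
#' @param seed Integer seed.
#' @param path Output CSV path.
#' @param unit Time unit label.
#' @return The generated `tto_sample`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' make_fixture("weibull", lambda = 0.00468, beta = 1.49, p = 0.98,
#'              n = 64, seed = 42, path = f)
#' read_cases(f)
#' @export
make_fixture <- function(family, lambda, beta = NULL, p, n, seed, path,
                         unit = "weeks") {
  scn <- tto_scenario(family, lambda = lambda, beta = beta, p = p, n = n,
                      n_reps = 1L, seed = as.integer(seed))
  s <- draw_truncated_sample(scn, seed = scn$seed)
  s$unit <- unit
  write_cases(s, path)
  meta <- list(family = family, lambda = lambda, beta = beta, p = p,
               n = n, tau = scn$tau, seed = as.integer(seed), unit = unit)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(s)
}
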