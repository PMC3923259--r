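#' Time-to-onset distribution families
#'
#' Constructs a parametric family for modelling the time-to-onset of an
#' adverse drug reaction. Three families are supported, chosen to cover the
#' hazard shapes commonly seen in pharmacovigilance: the exponential
#' (constant hazard), the Weibull (monotone increasing hazard for
#' `beta > 1`, decreasing for `beta < 1`) and the log-logistic (decreasing
#' for `beta < 1`, unimodal for `beta > 1`).
#'
#' The parameterization uses a rate-like scale parameter `lambda` (units
#' 1/time) that multiplies time directly, and a dimensionless shape `beta`
#' for the two-parameter families:
#' \describe{
#'   \item{exponential}{\eqn{f(x) = \lambda e^{-\lambda x}}}
#'   \item{weibull}{\eqn{f(x) = \lambda\beta(\lambda x)^{\beta-1}
#'     e^{-(\lambda x)^\beta}}}
#'   \item{loglogistic}{\eqn{f(x) = \lambda\beta(\lambda x)^{\beta-1} /
#'     (1 + (\lambda x)^\beta)^2}}
#' }
#' Note that `lambda` is *not* the scale parameter used by
#' [stats::dweibull()] (which would be `1/lambda`); conversions to other
#' conventions are the caller's responsibility. The support is strictly
#' positive time; `x = 0` is outside the support.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`.
#' @param lambda Scale parameter, `> 0`, units 1/time.
#' @param beta Shape parameter, `> 0`, required for the two-parameter
#'   families and disallowed for the exponential.
#' @return An object of class `"tto_family"`: a list with elements
#'   `family`, `lambda` and (except for the exponential) `beta`.
#' @seealso [dtto()], [ptto()], [qtto()], [tto_mean()]
#' @examples
#' w <- tto_family("weibull", lambda = 0.00468, beta = 1.49)
#' ptto(529, w)       # probability of onset within 529 weeks
#' tto_mean(w)        # expected time-to-onset (weeks)
#' @export
tto_family <- function(family = c("exponential", "weibull", "loglogistic"),
                       lambda, beta = NULL) {
  family <- match.arg(family)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("`lambda` must be a single finite positive number", call. = FALSE)
  }
  if (family == "exponential") {
    if (!is.null(beta)) {
      stop("the exponential family has no shape parameter `beta`",
           call. = FALSE)
    }
  } else {
    if (is.null(beta) || !is.numeric(beta) || length(beta) != 1L ||
        !is.finite(beta) || beta <= 0) {
      stop("`beta` must be a single finite positive number for the ",
           family, " family", call. = FALSE)
    }
  }
  structure(
    list(family = family, lambda = as.numeric(lambda),
         beta = if (!is.null(beta)) as.numeric(beta)),
    class = "tto_family"
  )
}

#' @export
print.tto_family <- function(x, ...) {
  cat("<tto_family> ", x$family, ": lambda = ", format(x$lambda),
      if (!is.null(x$beta)) paste0(", beta = ", format(x$beta)), "\n",
      sep = "")
  invisible(x)
}

# named parameter vector (lambda[, beta])
.theta <- function(spec) {
  if (spec$family == "exponential") c(lambda = spec$lambda)
  else c(lambda = spec$lambda, beta = spec$beta)
}

.check_spec <- function(spec) {
  if (!inherits(spec, "tto_family")) {
    stop("`spec` must be a `tto_family` object", call. = FALSE)
  }
  invisible(spec)
}

.check_positive_time <- function(x, what = "x") {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("`", what, "` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("`", what, "` must be strictly positive and finite; the support ",
         "of every family is x > 0", call. = FALSE)
  }
  invisible(x)
}

#' Density, distribution, quantile and mean of time-to-onset families
#'
#' Closed-form density, cumulative distribution function, quantile function
#' and mean for [tto_family()] objects. The log-density is evaluated
#' directly (not as `log(f)`), so it remains finite where `f` underflows —
#' a requirement for likelihood evaluation at extreme draws.
#'
#' `tto_mean()` returns the expectation: `1/lambda` (exponential),
#' `gamma(1 + 1/beta)/lambda` (Weibull) and
#' `(pi/beta) / (lambda * sin(pi/beta))` (log-logistic, defined only for
#' `beta > 1`). When the mean does not exist (log-logistic with
#' `beta <= 1`), `NA_real_` is returned with a warning of class
#' `"tto_undefined_mean"` so callers can distinguish a heavy tail from a
#' numerical accident.
#'
#' @param x,q Vector of strictly positive times.
#' @param p Vector of probabilities in (0, 1).
#' @param spec A [tto_family()] object.
#' @param log,log.p Return log-density / log-probability.
#' @param lower.tail If `FALSE`, return the survival function.
#' @return `dtto`, `ptto`: numeric vectors; `qtto`: positive times;
#'   `tto_mean`: a single positive number or `NA_real_` (with warning) when
#'   undefined.
#' @examples
#' ll <- tto_family("loglogistic", lambda = 1, beta = 2)
#' dtto(1, ll)   # 0.5
#' ptto(1, ll)   # 0.5
#' qtto(0.5, ll) # 1
#' @export
dtto <- function(x, spec, log = FALSE) {
  .check_spec(spec)
  .check_positive_time(x)
  lam <- spec$lambda
  bet <- spec$beta
  lx <- log(lam) + log(x)
  ld <- switch(spec$family,
    exponential = log(lam) - lam * x,
    weibull = {
      a <- bet * lx
      z <- ifelse(a > 700, Inf, exp(a))
      log(lam) + log(bet) + (bet - 1) * lx - z
    },
    loglogistic = {
      a <- bet * lx
      # -2*log(1+z) computed stably on both tails of a
      log(lam) + log(bet) + (bet - 1) * lx -
        2 * ifelse(a > 0, a + log1p(exp(-a)), log1p(exp(a)))
    }
  )
  if (log) ld else exp(ld)
}

#' @rdname dtto
#' @export
ptto <- function(q, spec, lower.tail = TRUE, log.p = FALSE) {
  .check_spec(spec)
  .check_positive_time(q, "q")
  lam <- spec$lambda
  bet <- spec$beta
  lF <- switch(spec$family,
    exponential = log(-expm1(-lam * q)),
    weibull = {
      a <- bet * (log(lam) + log(q))
      z <- ifelse(a > 700, Inf, exp(a))
      ifelse(is.infinite(z), 0, log(-expm1(-z)))
    },
    loglogistic = stats::plogis(bet * (log(lam) + log(q)), log.p = TRUE)
  )
  if (!lower.tail) {
    lF <- log(-expm1(pmin(lF, 0)))  # log survival
  }
  if (log.p) lF else exp(lF)
}

#' @rdname dtto
#' @export
qtto <- function(p, spec) {
  .check_spec(spec)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  lam <- spec$lambda
  bet <- spec$beta
  switch(spec$family,
    exponential = -log1p(-p) / lam,
    weibull = (-log1p(-p))^(1 / bet) / lam,
    loglogistic = (p / (1 - p))^(1 / bet) / lam
  )
}

#' @rdname dtto
#' @export
tto_mean <- function(spec) {
  .check_spec(spec)
  switch(spec$family,
    exponential = 1 / spec$lambda,
    weibull = gamma(1 + 1 / spec$beta) / spec$lambda,
    loglogistic = {
      if (spec$beta <= 1) {
        warning(warningCondition(
          paste0("the log-logistic mean is undefined for shape beta <= 1 ",
                 "(beta = ", format(spec$beta), "); returning NA"),
          class = c("tto_undefined_mean", "warning", "condition")
        ))
        return(NA_real_)
      }
      b <- pi / spec$beta
      b / (spec$lambda * sin(b))
    }
  )
}
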