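#' Declarative distribution specifications
#'
#' A `uf_dist` describes a sampling law for a duration in minutes without
#' fixing how it is sampled. Seven kinds cover everything the simulator needs:
#'
#' * `dist_triangular(min, mode, max)` — e.g. the TRIA(1, 5, 9) setup phase
#'   between a patient's entry into the room and the first uploaded image.
#' * `dist_beta_scaled(offset, scale, shape1, shape2)` — `offset + scale * X`
#'   with `X ~ Beta(shape1, shape2)`, the Arena `o + s * BETA(a1, a2)`
#'   convention.
#' * `dist_weibull_scaled(offset, scale, shape)` — `offset + W` with
#'   `W ~ Weibull(shape, scale)`, the Arena `o + WEIB(scale, shape)`
#'   convention (mean `offset + scale * gamma(1 + 1/shape)`).
#' * `dist_exponential(mean)` — exponential inter-arrival stand-in.
#' * `dist_deterministic(value)` — a constant.
#' * `dist_empirical(values, probs)` — a continuous piecewise-linear CDF
#'   through the breakpoints `(values[i], probs[i])`, `probs` ending at 1
#'   (the Arena CONT style for empirical inter-arrival data).
#' * `dist_mixture(weights, components)` — finite mixture of `uf_dist`
#'   components, e.g. the fitted prostate examination-time hybrid
#'   `0.485 (3 + 7 Beta(1.9, 1.16)) + 0.424 (10 + Weib(3.46, 1.23)) +
#'   0.091 (20 + Weib(6.99, 1.29))`.
#'
#' All constructors validate their parameters (mixture weights must sum to 1
#' within 1e-9, triangular needs `min <= mode <= max`, empirical breakpoints
#' must be strictly increasing in value and probability) and name the
#' offending field on failure.
#'
#' @param min,mode,max Triangular parameters, minutes.
#' @param offset,scale Location/scale applied to the Beta or Weibull core.
#' @param shape1,shape2,shape Shape parameters.
#' @param mean Mean of the exponential, minutes.
#' @param value The constant value.
#' @param values,probs Empirical CDF breakpoints: values strictly increasing,
#'   cumulative probabilities non-decreasing from >= 0 to exactly 1.
#' @param weights,components Mixture weights (positive, summing to 1) and a
#'   list of component `uf_dist` objects.
#' @return A `uf_dist` object.
#' @name uf_dist
NULL

new_dist <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "uf_dist")
}

#' @rdname uf_dist
#' @export
dist_triangular <- function(min, mode, max) {
  check_number(min, "min"); check_number(mode, "mode"); check_number(max, "max")
  if (!(min <= mode && mode <= max)) {
    stop_input("triangular requires min <= mode <= max (got %g, %g, %g).", min, mode, max)
  }
  new_dist("triangular", min = min, mode = mode, max = max)
}

#' @rdname uf_dist
#' @export
dist_beta_scaled <- function(offset, scale, shape1, shape2) {
  check_number(offset, "offset"); check_number(scale, "scale", positive = TRUE)
  check_number(shape1, "shape1", positive = TRUE); check_number(shape2, "shape2", positive = TRUE)
  new_dist("beta_scaled", offset = offset, scale = scale, shape1 = shape1, shape2 = shape2)
}

#' @rdname uf_dist
#' @export
dist_weibull_scaled <- function(offset, scale, shape) {
  check_number(offset, "offset"); check_number(scale, "scale", positive = TRUE)
  check_number(shape, "shape", positive = TRUE)
  new_dist("weibull_scaled", offset = offset, scale = scale, shape = shape)
}

#' @rdname uf_dist
#' @export
dist_exponential <- function(mean) {
  check_number(mean, "mean", positive = TRUE)
  new_dist("exponential", mean = mean)
}

#' @rdname uf_dist
#' @export
dist_deterministic <- function(value) {
  check_number(value, "value")
  new_dist("deterministic", value = value)
}

#' @rdname uf_dist
#' @export
dist_empirical <- function(values, probs) {
  if (length(values) != length(probs) || length(values) < 2L) {
    stop_input("empirical requires matching `values`/`probs` of length >= 2.")
  }
  if (any(diff(values) <= 0)) stop_input("empirical `values` must be strictly increasing.")
  if (any(diff(probs) <= 0)) stop_input("empirical `probs` must be strictly increasing.")
  if (probs[1] < 0 || abs(probs[length(probs)] - 1) > 1e-9) {
    stop_input("empirical `probs` must rise to exactly 1 (last is %g).", probs[length(probs)])
  }
  new_dist("empirical", values = as.numeric(values), probs = as.numeric(probs))
}

#' @rdname uf_dist
#' @export
dist_mixture <- function(weights, components) {
  if (!is.list(components) || !all(vapply(components, inherits, TRUE, "uf_dist"))) {
    stop_input("`components` must be a list of uf_dist objects.")
  }
  if (length(weights) != length(components) || length(weights) == 0L) {
    stop_input("`weights` must match `components` in length.")
  }
  if (any(weights <= 0)) stop_input("mixture `weights` must all be positive.")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_input("mixture `weights` must sum to 1 within 1e-9 (sum is %.12g).", sum(weights))
  }
  new_dist("mixture", weights = as.numeric(weights), components = components)
}

#' @export
print.uf_dist <- function(x, ...) {
  cat(format_dist(x), "\n")
  invisible(x)
}

format_dist <- function(d) {
  switch(d$kind,
    triangular = sprintf("TRIA(%g, %g, %g)", d$min, d$mode, d$max),
    beta_scaled = sprintf("%g + %g*BETA(%g, %g)", d$offset, d$scale, d$shape1, d$shape2),
    weibull_scaled = sprintf("%g + WEIB(%g, %g)", d$offset, d$scale, d$shape),
    exponential = sprintf("EXPO(mean %g)", d$mean),
    deterministic = sprintf("CONST(%g)", d$value),
    empirical = sprintf("EMP(%d pts on [%g, %g])", length(d$values),
                        d$values[1], d$values[length(d$values)]),
    mixture = paste(sprintf("%g*(%s)", d$weights,
                            vapply(d$components, format_dist, "")), collapse = " + ")
  )
}

#' Sample from a distribution specification
#'
#' Draws `n` variates from `spec` using (and advancing) the given substream,
#' so repeated calls with a freshly constructed stream reproduce the same
#' sequence. Every draw respects the spec's lower support bound (offsets
#' included): e.g. every draw from the fitted prostate mixture is >= 3.
#'
#' @param spec A [uf_dist] object.
#' @param n Number of draws.
#' @param stream A [rand_stream()]; one is created from seed 0 if omitted
#'   (only convenient for interactive use — simulations always pass streams).
#' @return Numeric vector of length `n`, in minutes.
#' @examples
#' sample_dist(dist_triangular(1, 5, 9), 5, rand_stream(1, "setup"))
#' @export
sample_dist <- function(spec, n = 1, stream = rand_stream(0, "adhoc")) {
  validate_dist(spec)
  check_number(n, "n", min = 0)
  draw_stream(stream, function() sample_dist_impl(spec, n))
}

validate_dist <- function(spec) {
  if (!inherits(spec, "uf_dist")) stop_input("`spec` must be a uf_dist object.")
  invisible(spec)
}

# Runs inside a stream context: plain r* calls only.
sample_dist_impl <- function(d, n) {
  if (n == 0) return(numeric(0))
  switch(d$kind,
    deterministic = rep(d$value, n),
    exponential = rexp(n, rate = 1 / d$mean),
    beta_scaled = d$offset + d$scale * rbeta(n, d$shape1, d$shape2),
    weibull_scaled = d$offset + rweibull(n, shape = d$shape, scale = d$scale),
    triangular = qtriangular(runif(n), d$min, d$mode, d$max),
    empirical = emp_quantile(runif(n), d$values, d$probs),
    mixture = {
      k <- length(d$weights)
      idx <- findInterval(runif(n), cumsum(d$weights)[-k]) + 1L
      out <- numeric(n)
      for (j in seq_len(k)) {
        sel <- idx == j
        if (any(sel)) out[sel] <- sample_dist_impl(d$components[[j]], sum(sel))
      }
      out
    }
  )
}

qtriangular <- function(u, a, m, b) {
  if (b == a) return(rep(a, length(u)))
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

emp_quantile <- function(u, values, probs) {
  # piecewise-linear CDF through (values, probs); CDF is 0 below values[1]
  p <- c(if (probs[1] > 0) 0 else NULL, probs)
  v <- c(if (probs[1] > 0) values[1] else NULL, values)
  stats::approx(p, v, xout = pmin(pmax(u, p[1]), 1), ties = "ordered")$y
}

#' Analytic mean of a distribution specification
#'
#' Closed-form mean for every kind: triangular `(min+mode+max)/3`; scaled
#' Beta `offset + scale*a1/(a1+a2)`; scaled Weibull
#' `offset + scale*gamma(1+1/shape)`; mixtures are weight-sums of component
#' means; empirical CDFs use the trapezoid mean of the piecewise-linear CDF.
#'
#' @param spec A [uf_dist] object.
#' @return Mean in minutes.
#' @examples
#' dist_mean(dist_triangular(1, 5, 9))  # 5
#' @export
dist_mean <- function(spec) {
  validate_dist(spec)
  d <- spec
  switch(d$kind,
    deterministic = d$value,
    exponential = d$mean,
    triangular = (d$min + d$mode + d$max) / 3,
    beta_scaled = d$offset + d$scale * d$shape1 / (d$shape1 + d$shape2),
    weibull_scaled = d$offset + d$scale * gamma(1 + 1 / d$shape),
    mixture = sum(d$weights * vapply(d$components, dist_mean, 0)),
    empirical = {
      p <- c(if (d$probs[1] > 0) 0 else NULL, d$probs)
      v <- c(if (d$probs[1] > 0) d$values[1] else NULL, d$values)
      sum(diff(p) * (head(v, -1) + tail(v, -1)) / 2)
    }
  )
}

#' Exact CDF of a distribution specification
#'
#' Evaluates `P(X <= q)` under `spec`; mixture and empirical CDFs are
#' evaluated exactly (no simulation). Used by [ks_check()].
#'
#' @param spec A [uf_dist] object.
#' @param q Numeric vector of quantile points.
#' @return Vector of probabilities.
#' @export
dist_cdf <- function(spec, q) {
  validate_dist(spec)
  d <- spec
  switch(d$kind,
    deterministic = as.numeric(q >= d$value),
    exponential = stats::pexp(q, rate = 1 / d$mean),
    beta_scaled = stats::pbeta((q - d$offset) / d$scale, d$shape1, d$shape2),
    weibull_scaled = stats::pweibull(pmax(q - d$offset, 0), d$shape, d$scale),
    triangular = ptriangular(q, d$min, d$mode, d$max),
    empirical = {
      p <- c(if (d$probs[1] > 0) 0 else NULL, d$probs)
      v <- c(if (d$probs[1] > 0) d$values[1] else NULL, d$values)
      out <- stats::approx(v, p, xout = q, yleft = 0, yright = 1, ties = "ordered")$y
      out
    },
    mixture = {
      out <- numeric(length(q))
      for (j in seq_along(d$weights)) {
        out <- out + d$weights[j] * dist_cdf(d$components[[j]], q)
      }
      out
    }
  )
}

ptriangular <- function(q, a, m, b) {
  out <- numeric(length(q))
  out[q >= b] <- 1
  i <- q > a & q < m
  out[i] <- (q[i] - a)^2 / ((b - a) * (m - a))
  i <- q >= m & q < b
  out[i] <- 1 - (b - q[i])^2 / ((b - a) * (b - m))
  out
}

#' Quantile function of a distribution specification
#'
#' Inverse of [dist_cdf()]. Closed form for all kinds except mixtures, which
#' are inverted by bisection to 1e-10.
#'
#' @param spec A [uf_dist] object.
#' @param p Vector of probabilities in (0, 1).
#' @return Vector of quantiles (minutes).
#' @export
dist_quantile <- function(spec, p) {
  validate_dist(spec)
  if (any(p < 0 | p > 1)) stop_input("`p` must lie in [0, 1].")
  d <- spec
  switch(d$kind,
    deterministic = rep(d$value, length(p)),
    exponential = stats::qexp(p, rate = 1 / d$mean),
    beta_scaled = d$offset + d$scale * stats::qbeta(p, d$shape1, d$shape2),
    weibull_scaled = d$offset + stats::qweibull(p, d$shape, d$scale),
    triangular = qtriangular(p, d$min, d$mode, d$max),
    empirical = emp_quantile(p, d$values, d$probs),
    mixture = vapply(p, function(pp) mixture_quantile(d, pp), 0)
  )
}

mixture_quantile <- function(d, p) {
  los <- vapply(d$components, function(c) dist_quantile(c, 0), 0)
  his <- vapply(d$components, function(c) dist_quantile(c, 1 - 1e-12), 0)
  lo <- min(los); hi <- max(his)
  if (p <= 0) return(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (dist_cdf(d, mid) < p) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

#' One-sample Kolmogorov-Smirnov check against a specification
#'
#' Computes the exact one-sample K-S statistic of `samples` against the
#' spec's CDF (mixtures and empirical CDFs evaluated exactly) and compares it
#' with the asymptotic critical value `sqrt(-log(alpha/2)/2) / sqrt(n)`.
#' This is the self-check counterpart of the distribution-fitting goodness
#' tests used to select the input distributions.
#'
#' @param samples Numeric vector, at least 20 observations.
#' @param spec A [uf_dist] object.
#' @param alpha Significance level (default 0.05).
#' @return A list with `statistic`, `critical`, and logical `pass`.
#' @export
ks_check <- function(samples, spec, alpha = 0.05) {
  validate_dist(spec)
  if (length(samples) == 0L) stop_input("`samples` is empty.")
  if (length(samples) < 20L) stop_input("ks_check needs at least 20 samples (got %d).", length(samples))
  check_number(alpha, "alpha", positive = TRUE)
  x <- sort(samples)
  n <- length(x)
  Fx <- dist_cdf(spec, x)
  d_plus <- max(seq_len(n) / n - Fx)
  d_minus <- max(Fx - (seq_len(n) - 1) / n)
  stat <- max(d_plus, d_minus)
  crit <- sqrt(-log(alpha / 2) / 2) / sqrt(n)
  list(statistic = stat, critical = crit, pass = stat < crit)
}
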