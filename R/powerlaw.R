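#' Degree distribution table
#'
#' Tabulates the total (in + out) degree of every node with percent and
#' cumulative-percent columns (4 decimal places). Degree counts always satisfy
#' `sum(freq) = N` and `sum(degree * freq) = 2m`.
#'
#' @param graph A [pathway_graph()].
#' @return A data frame with columns `degree`, `n`, `percent`, `cum_n`,
#'   `cum_percent`; the raw per-node degree sample is attached as
#'   `attr(, "sample")`.
#' @export
degree_distribution <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  sample <- degree_sequence(graph, "total")
  if (!length(sample)) {
    out <- data.frame(degree = integer(0), n = integer(0), percent = numeric(0),
                      cum_n = integer(0), cum_percent = numeric(0))
    attr(out, "sample") <- integer(0)
    return(out)
  }
  tab <- table(sample)
  deg <- as.integer(names(tab))
  cnt <- as.integer(tab)
  n <- length(sample)
  out <- data.frame(
    degree = deg,
    n = cnt,
    percent = .round4(100 * cnt / n),
    cum_n = cumsum(cnt),
    cum_percent = .round4(100 * cumsum(cnt) / n)
  )
  attr(out, "sample") <- unname(sample)
  out
}

#' Power-law scale parameter by continuous-approximation maximum likelihood
#'
#' Estimates the scale parameter of a Pareto tail from the sample values at or
#' above `xmin`:
#' `alpha_hat = 1 + n_tail / sum(log(x_i / (xmin - 1/2)))`,
#' the continuous-approximation MLE in which integer observations are treated
#' as continuous values binned at half-integer boundaries. With
#' `discrete = FALSE` the shift is dropped (`log(x_i / xmin)`), the exact
#' continuous-data MLE.
#'
#' With `exact = TRUE` (integer data only) the estimate instead maximizes the
#' exact discrete likelihood `P[X = x] = x^-alpha / zeta(alpha, xmin)` with a
#' Hurwitz-zeta normalization — the standard estimator for integer degrees,
#' unbiased down to `xmin = 1` where the continuous approximation is not.
#'
#' @param x Numeric sample (e.g. node degrees).
#' @param xmin Tail threshold (`>= 1`, and `> 0.5` in discrete mode).
#' @param discrete Integer data with the half-shift convention? Default `TRUE`.
#' @param exact Use the zeta-normalized discrete MLE (requires
#'   `discrete = TRUE`)? Default `FALSE`.
#' @return The estimate `alpha_hat` (always `> 1`).
#' @examples
#' fit_alpha(c(2, 2, 3, 4), xmin = 2)  # 2.7783
#' @seealso [select_xmin()], [fit_powerlaw()]
#' @export
fit_alpha <- function(x, xmin, discrete = TRUE, exact = FALSE) {
  stopifnot(is.numeric(x), length(xmin) == 1L, xmin >= 1)
  tail <- x[x >= xmin]
  if (length(tail) < 2L) stop("power-law tail too small: need >= 2 values at or above xmin")
  if (exact) {
    if (!discrete) stop("the exact zeta-normalized MLE applies to discrete data only")
    n <- length(tail)
    slog <- sum(log(tail))
    nll <- function(a) n * log(.hurwitz_zeta(a, xmin)) + a * slog
    return(stats::optimize(nll, c(1.0001, 25))$minimum)
  }
  shift <- if (discrete) xmin - 0.5 else xmin
  1 + length(tail) / sum(log(tail / shift))
}

# Hurwitz zeta(a, q) = sum_{k>=0} (q+k)^-a by direct summation with an
# Euler-Maclaurin tail correction; vectorized over q
.hurwitz_zeta <- function(a, q, nterms = 500L) {
  k <- 0:(nterms - 1L)
  vapply(q, function(qi) {
    head_sum <- sum((qi + k)^(-a))
    m <- qi + nterms
    head_sum + m^(1 - a) / (a - 1) + 0.5 * m^(-a) + a * m^(-a - 1) / 12
  }, numeric(1))
}

#' Kolmogorov-Smirnov distance of a fitted power-law tail
#'
#' The sup distance `L = max |S(x) - P(x)|` over the observed tail values,
#' where `S` is the empirical tail CCDF (`Pr[X >= x]` among values `>= xmin`)
#' and `P` the fitted model CCDF. In discrete mode the model CCDF uses the
#' half-integer binning of the estimator,
#' `P[X >= x] = ((x - 1/2) / (xmin - 1/2))^-(alpha - 1)`; in continuous mode
#' `P[X >= x] = (x / xmin)^-(alpha - 1)` and both one-sided limits of the
#' empirical step function are compared.
#'
#' With `exact = TRUE` the model CCDF is the zeta-normalized discrete tail
#' `P[X >= x] = zeta(alpha, x) / zeta(alpha, xmin)`, matching the exact MLE of
#' [fit_alpha()].
#'
#' @param x Numeric sample.
#' @param alpha Fitted scale parameter.
#' @param xmin Tail threshold.
#' @param discrete Same convention flag as [fit_alpha()].
#' @param exact Zeta-normalized discrete model CCDF? Default `FALSE`.
#' @return The KS distance `L` in `[0, 1]`.
#' @export
ks_statistic <- function(x, alpha, xmin, discrete = TRUE, exact = FALSE) {
  stopifnot(is.numeric(x), alpha > 1, xmin >= 1)
  tail <- sort(x[x >= xmin])
  if (!length(tail)) stop("empty tail: no values at or above xmin")
  r <- rle(tail)
  v <- r$values
  cnt <- r$lengths
  n <- length(tail)
  s_ge <- rev(cumsum(rev(cnt))) / n  # empirical Pr[X >= v] over the tail
  if (exact) {
    if (!discrete) stop("the exact zeta-normalized model applies to discrete data only")
    p <- .hurwitz_zeta(alpha, v) / .hurwitz_zeta(alpha, xmin)
    max(abs(s_ge - p))
  } else if (discrete) {
    p <- ((v - 0.5) / (xmin - 0.5))^(-(alpha - 1))
    max(abs(s_ge - p))
  } else {
    p <- (v / xmin)^(-(alpha - 1))
    s_gt <- s_ge - cnt / n
    max(abs(s_ge - p), abs(s_gt - p))
  }
}

#' Select the tail threshold xmin by minimizing the KS distance
#'
#' Scans candidate thresholds over the distinct sample values (excluding the
#' largest, and any candidate whose tail holds fewer than 2 observations),
#' fits the scale parameter at each and computes the KS distance of the fitted
#' tail; the candidate minimizing the distance wins, with ties going to the
#' smallest threshold.
#'
#' @param x Numeric sample with at least 2 distinct values.
#' @param discrete,exact Convention flags, see [fit_alpha()].
#' @return A list with `xmin`, `alpha`, `ks` and `n_tail`.
#' @examples
#' deg <- c(rep(1, 14), rep(2, 12), rep(3, 5), rep(4, 2), 7)
#' select_xmin(deg)$xmin  # 2
#' @export
select_xmin <- function(x, discrete = TRUE, exact = FALSE) {
  stopifnot(is.numeric(x))
  v <- sort(unique(x))
  if (length(v) < 2L) stop("xmin selection needs at least 2 distinct sample values")
  cand <- v[-length(v)]
  cand <- cand[cand >= 1]
  cand <- cand[vapply(cand, function(u) sum(x >= u) >= 2L, logical(1))]
  if (!length(cand)) stop("no admissible xmin candidate (tails too small)")
  fits <- lapply(cand, function(u) {
    a <- fit_alpha(x, u, discrete = discrete, exact = exact)
    list(xmin = u, alpha = a,
         ks = ks_statistic(x, a, u, discrete = discrete, exact = exact))
  })
  ks <- vapply(fits, `[[`, numeric(1), "ks")
  best <- fits[[which.min(ks)]]  # which.min takes the first = smallest xmin on ties
  best$n_tail <- sum(x >= best$xmin)
  best
}

#' Draw samples from a power-law (Pareto) tail
#'
#' Inverse-transform sampling from `P[X >= x] = (x / xmin)^-(alpha - 1)`.
#' Discrete mode rounds through the half-shift,
#' `floor((xmin - 1/2) * (1 - u)^(-1/(alpha - 1)) + 1/2)`, matching the
#' binning convention of the estimator.
#'
#' With `exact = TRUE` integer draws come from the zeta-normalized discrete
#' law `P[X = k] = k^-alpha / zeta(alpha, xmin)` itself (inverse-CDF over a
#' tabulated CCDF), the generating model matched to the exact MLE of
#' [fit_alpha()].
#'
#' @param n Number of draws (`>= 1`).
#' @param alpha Scale parameter (`> 1`).
#' @param xmin Tail threshold.
#' @param discrete Integer draws? Default `TRUE`.
#' @param exact Draw from the zeta-normalized discrete law? Default `FALSE`.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return A numeric (or integer-valued) vector of length `n`, all `>= xmin`.
#' @export
sample_powerlaw <- function(n, alpha, xmin = 1, discrete = TRUE,
                            exact = FALSE, seed = NULL) {
  stopifnot(length(n) == 1L, n >= 1, xmin >= 1)
  if (alpha <= 1) stop("power-law sampling requires alpha > 1")
  if (exact && !discrete) stop("exact sampling is defined for discrete draws only")
  .with_seed(seed, {
    u <- stats::runif(n)
    if (exact) {
      # pmf support truncated where the residual mass is negligible
      kmax <- max(1e6, xmin + 10)
      k <- seq(from = xmin, to = kmax)
      pmf <- k^(-alpha)
      cdf <- cumsum(pmf) / (sum(pmf) + .hurwitz_zeta(alpha, kmax + 1))
      k[pmin(findInterval(u, cdf) + 1L, length(k))]
    } else if (discrete) {
      floor((xmin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
    } else {
      xmin * (1 - u)^(-1 / (alpha - 1))
    }
  })
}

#' Semi-parametric bootstrap p-value for the power-law fit
#'
#' Generates `n_boot` datasets of the original sample size: each observation
#' is drawn from the fitted tail model with probability `n_tail/n` and
#' resampled from the empirical body (values below `xmin`) otherwise. Each
#' dataset is refitted — threshold selection included — and its KS distance
#' computed; the p-value is the fraction of bootstrap distances exceeding the
#' observed one. Large p (near 1) means the observed distance is typical of
#' the fitted model's own fluctuations; `p <= 0.1` is taken as evidence
#' against the power law and sets the rejection flag.
#'
#' @param x The original sample.
#' @param fit A [fit_powerlaw()] object or a list with `alpha`, `xmin`, `ks`
#'   and optionally `discrete`.
#' @param n_boot Number of bootstrap datasets (`>= 1`), default 1000.
#' @param seed Optional integer seed.
#' @return A list with `p_value`, `n_boot`, `reject` (`p <= 0.1`) and the
#'   bootstrap distances `ks_boot`.
#' @export
bootstrap_pvalue <- function(x, fit, n_boot = 1000L, seed = NULL) {
  stopifnot(is.numeric(x))
  if (n_boot < 1L) stop("n_boot must be >= 1")
  alpha <- fit$alpha
  xmin <- fit$xmin
  L_obs <- fit$ks
  discrete <- fit$discrete %||% TRUE
  stopifnot(is.numeric(alpha), is.numeric(xmin), is.numeric(L_obs))
  n <- length(x)
  body <- x[x < xmin]
  p_tail <- 1 - length(body) / n
  .with_seed(seed, {
    ks_boot <- vapply(seq_len(n_boot), function(b) {
      k <- stats::rbinom(1L, n, p_tail)
      xb <- numeric(0)
      if (k > 0L) xb <- sample_powerlaw(k, alpha, xmin, discrete = discrete)
      if (k < n) xb <- c(xb, sample(body, n - k, replace = TRUE))
      tryCatch(select_xmin(xb, discrete = discrete,
                           exact = fit$exact %||% FALSE)$ks,
               error = function(e) NA_real_)  # degenerate draw: all values equal
    }, numeric(1))
    ok <- !is.na(ks_boot)
    p <- mean(ks_boot[ok] > L_obs)
    list(p_value = p, n_boot = as.integer(n_boot), reject = p <= 0.1,
         ks_boot = ks_boot)
  })
}

#' Fit a power-law model to a degree sample
#'
#' The front door of the scale-free analysis: selects the tail threshold by
#' KS minimization (or uses a fixed `xmin`), estimates the scale parameter by
#' the continuous-approximation MLE, and optionally runs the semi-parametric
#' bootstrap goodness-of-fit test. Returns a classed model object with
#' `print()`, `summary()`, `coef()`, `plot()` and `simulate()` methods.
#'
#' @param x Numeric sample, typically the total-degree sequence of a network
#'   (see [degree_distribution()]).
#' @param xmin `NULL` (default) to select the threshold automatically, or a
#'   fixed value.
#' @param discrete,exact Estimator conventions, see [fit_alpha()].
#' @param n_boot Bootstrap datasets for the goodness-of-fit p-value; 0 (the
#'   default) skips the test.
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `powerlaw_fit` with components `alpha`, `xmin`,
#'   `ks`, `n_tail`, `n`, `p_value`, `reject`, `n_boot`, `discrete`, `sample`.
#' @examples
#' deg <- c(rep(1, 14), rep(2, 12), rep(3, 5), rep(4, 2), 7)
#' fit <- fit_powerlaw(deg)
#' fit
#' coef(fit)
#' @export
fit_powerlaw <- function(x, xmin = NULL, discrete = TRUE, exact = FALSE,
                         n_boot = 0L, seed = NULL) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (is.null(xmin)) {
    sel <- select_xmin(x, discrete = discrete, exact = exact)
  } else {
    a <- fit_alpha(x, xmin, discrete = discrete, exact = exact)
    sel <- list(xmin = xmin, alpha = a,
                ks = ks_statistic(x, a, xmin, discrete = discrete, exact = exact),
                n_tail = sum(x >= xmin))
  }
  out <- structure(
    list(alpha = sel$alpha, xmin = sel$xmin, ks = sel$ks,
         n_tail = sel$n_tail, n = length(x), p_value = NA_real_,
         reject = NA, n_boot = 0L, discrete = discrete, exact = exact,
         seed = seed, sample = as.numeric(x), call = match.call()),
    class = "powerlaw_fit"
  )
  if (n_boot > 0L) {
    bt <- bootstrap_pvalue(x, out, n_boot = n_boot, seed = seed)
    out$p_value <- bt$p_value
    out$reject <- bt$reject
    out$n_boot <- bt$n_boot
  }
  out
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law (Pareto tail) fit, %s convention\n",
              if (x$discrete) "discrete half-shift" else "continuous"))
  cat(sprintf("  alpha = %.2f, xmin = %s (tail n = %d of %d)\n",
              x$alpha, format(x$xmin), x$n_tail, x$n))
  cat(sprintf("  KS distance L = %.4f\n", x$ks))
  if (!is.na(x$p_value)) {
    cat(sprintf("  bootstrap p = %.4f (%d datasets): %s\n", x$p_value, x$n_boot,
                if (x$reject) "rejects the power law (p <= 0.1)"
                else "consistent with a power law"))
  }
  invisible(x)
}

#' @export
summary.powerlaw_fit <- function(object, ...) {
  out <- object
  out$ccdf <- ccdf_table(object)
  class(out) <- "summary.powerlaw_fit"
  out
}

#' @export
print.summary.powerlaw_fit <- function(x, ...) {
  class(x) <- "powerlaw_fit"
  print(x)
  cat("\nLog-log CCDF (empirical vs fitted):\n")
  print(x$ccdf, row.names = FALSE)
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(alpha = object$alpha, xmin = object$xmin)
}

#' Empirical and fitted complementary CDF table
#'
#' One row per distinct sample value: the empirical share of observations at
#' or above it and the fitted model CCDF (scaled by the tail share so both are
#' unconditional), the content of a log-log degree-distribution plot.
#'
#' @param fit A [fit_powerlaw()] object.
#' @return A data frame with columns `x`, `empirical`, `fitted` (`NA` below
#'   `xmin`).
#' @export
ccdf_table <- function(fit) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  s <- fit$sample
  v <- sort(unique(s))
  emp <- vapply(v, function(u) mean(s >= u), numeric(1))
  share <- fit$n_tail / fit$n
  shift <- if (fit$discrete) 0.5 else 0
  fitted <- ifelse(
    v >= fit$xmin,
    share * ((v - shift) / (fit$xmin - shift))^(-(fit$alpha - 1)),
    NA_real_
  )
  data.frame(x = v, empirical = emp, fitted = fitted)
}

#' @export
plot.powerlaw_fit <- function(x, ...) {
  tab <- ccdf_table(x)
  graphics::plot(tab$x, tab$empirical, log = "xy", pch = 15,
                 xlab = "degree x", ylab = "Pr[X >= x]",
                 main = "Degree distribution and fitted power law", ...)
  ok <- !is.na(tab$fitted)
  graphics::lines(tab$x[ok], tab$fitted[ok], lty = 2)
  graphics::legend("bottomleft", bty = "n", pch = c(15, NA), lty = c(NA, 2),
                   legend = c("empirical CCDF",
                              sprintf("fitted tail (alpha = %.2f, xmin = %s)",
                                      x$alpha, format(x$xmin))))
  invisible(x)
}

#' @export
simulate.powerlaw_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$n
  body <- object$sample[object$sample < object$xmin]
  p_tail <- object$n_tail / n
  .with_seed(seed, {
    out <- replicate(nsim, {
      k <- stats::rbinom(1L, n, p_tail)
      xb <- numeric(0)
      if (k > 0L) xb <- sample_powerlaw(k, object$alpha, object$xmin,
                                        discrete = object$discrete)
      if (k < n) xb <- c(xb, sample(body, n - k, replace = TRUE))
      sample(xb)
    })
    as.data.frame(out)
  })
}
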