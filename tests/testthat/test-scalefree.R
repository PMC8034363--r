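core_degree_sample <- function() c(rep(1, 14), rep(2, 12), rep(3, 5), rep(4, 2), 7)

test_that("degree distributions conserve node and endpoint counts", {
  cyc <- pathway_graph(c("a", "b", "c"),
                       data.frame(source = c("a", "b", "c"),
                                  target = c("b", "c", "a")))
  dd <- degree_distribution(cyc)
  expect_equal(dd$degree, 2L)
  expect_equal(dd$n, 3L)
  expect_equal(dd$cum_percent, 100)

  for (seed in 901:910) {
    g <- random_test_digraph(seed)
    d <- degree_distribution(g)
    expect_equal(sum(d$n), n_nodes(g))
    expect_equal(sum(d$degree * d$n), 2L * n_arcs(g))
  }
  expect_equal(nrow(degree_distribution(pathway_graph())), 0L)
})

test_that("the tail MLE reproduces hand-evaluated estimates", {
  expect_equal(round(fit_alpha(c(2, 2, 3, 4), 2), 4), 2.7783)
  expect_equal(round(fit_alpha(core_degree_sample(), 2), 4), 2.9194)
  expect_equal(round(fit_alpha(c(2, 2), 2), 4), 4.4761)
  expect_equal(fit_alpha(c(2, 2), 2), 1 + 2 / (2 * log(4 / 3)))
  expect_error(fit_alpha(c(1, 1, 5), 5), "tail too small")
})

test_that("adding heavier tail values strictly decreases the estimate", {
  x <- c(2, 2, 3, 4)
  a0 <- fit_alpha(x, 2)
  for (extra in c(6, 10, 50)) {
    a1 <- fit_alpha(c(x, extra), 2)
    expect_lt(a1, a0)
    a0 <- a1
  }
})

test_that("the KS distance equals a direct double-loop evaluation", {
  brute_ks <- function(x, alpha, xmin) {
    tail <- x[x >= xmin]
    worst <- 0
    for (v in unique(tail)) {
      s <- sum(tail >= v) / length(tail)
      p <- ((v - 0.5) / (xmin - 0.5))^(-(alpha - 1))
      worst <- max(worst, abs(s - p))
    }
    worst
  }
  for (seed in 921:930) {
    x <- sample_powerlaw(sample(50:200, 1), 2.4, 1, seed = seed)
    a <- fit_alpha(x, 1)
    expect_equal(ks_statistic(x, a, 1), brute_ks(x, a, 1))
    a2 <- fit_alpha(x, 2)
    expect_equal(ks_statistic(x, a2, 2), brute_ks(x, a2, 2))
  }
  expect_error(ks_statistic(c(1, 1), 2, 5), "empty tail")
})

test_that("samples placed at exact model quantiles have a vanishing KS distance", {
  n <- 400
  alpha <- 2.5
  u <- (seq_len(n) - 0.5) / n
  x <- 1 * (1 - u)^(-1 / (alpha - 1))  # continuous inverse-CDF positions
  expect_lte(ks_statistic(x, alpha, 1, discrete = FALSE), 1 / n)
})

test_that("xmin selection minimizes the KS distance with stated tie handling", {
  sel <- select_xmin(core_degree_sample())
  expect_equal(sel$xmin, 2)
  expect_equal(round(sel$alpha, 4), 2.9194)
  expect_equal(sel$n_tail, 20L)

  deg <- select_xmin(c(1, 1, 1, 5))
  expect_equal(deg$xmin, 1)  # only admissible candidate
  expect_error(select_xmin(c(3, 3, 3)), "2 distinct")

  # threshold recovery needs the generating model and the estimator to agree:
  # draws from the zeta-normalized law, fitted with the exact discrete MLE
  hits <- vapply(1:20, function(s) {
    x <- sample_powerlaw(5000, 2.5, 1, exact = TRUE, seed = 4000L + s)
    select_xmin(x, exact = TRUE)$xmin == 1
  }, logical(1))
  expect_gte(sum(hits), 18L)  # generator threshold recovered in >= 90% of seeds
})

test_that("the exact zeta-normalized MLE is unbiased at xmin = 1 and matches 3.28", {
  # the continuous-approximation estimator is biased at small integer xmin;
  # the exact discrete MLE is the standard remedy and, on the published core
  # degree tail at xmin = 2, reproduces the printed scale parameter 3.28
  expect_equal(round(fit_alpha(core_degree_sample(), 2, exact = TRUE), 2), 3.28)
  a <- vapply(1:5, function(s) {
    x <- sample_powerlaw(5000, 2.5, 1, exact = TRUE, seed = 4100L + s)
    fit_alpha(x, 1, exact = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(a) - 2.5), 0.05)
  expect_error(fit_alpha(c(1, 2, 3), 1, discrete = FALSE, exact = TRUE),
               "discrete data only")
})

test_that("power-law sampling is reproducible and respects its support", {
  x1 <- sample_powerlaw(100, 2.5, 2, seed = 1)
  x2 <- sample_powerlaw(100, 2.5, 2, seed = 1)
  expect_identical(x1, x2)
  expect_true(all(x1 >= 2))
  expect_equal(mean(x1 >= 2), 1)  # empirical CCDF at xmin is 1
  expect_equal(length(sample_powerlaw(1, 3, 1, seed = 9)), 1L)
  expect_error(sample_powerlaw(10, 1, 1), "alpha > 1")
  expect_error(sample_powerlaw(0, 2, 1), "n >= 1")

  for (s in 1:10) {
    x <- sample_powerlaw(5000, 2.5, 2, discrete = FALSE, seed = 6000L + s)
    expect_lt(abs(fit_alpha(x, 2, discrete = FALSE) - 2.5), 0.1)
  }
})

test_that("bootstrap p-values are probabilities with a coherent rejection flag", {
  x <- sample_powerlaw(120, 2.3, 1, seed = 51)
  fit <- fit_powerlaw(x)
  bt <- bootstrap_pvalue(x, fit, n_boot = 40, seed = 52)
  expect_gte(bt$p_value, 0)
  expect_lte(bt$p_value, 1)
  expect_identical(bt$reject, bt$p_value <= 0.1)
  expect_length(bt$ks_boot, 40L)
  expect_error(bootstrap_pvalue(x, fit, n_boot = 0), "n_boot")

  # data drawn from the fitted model itself: p is calibrated, not extreme
  m <- vapply(1:50, function(r) {
    xr <- sample_powerlaw(100, 2.5, 1, seed = 31000L + r)
    fr <- fit_powerlaw(xr)
    bootstrap_pvalue(xr, fr, n_boot = 50, seed = 32000L + r)$p_value
  }, numeric(1))
  expect_gte(mean(m), 0.35)
  expect_lte(mean(m), 0.65)
})

test_that("the fitted model object behaves like a classic S3 fit", {
  x <- core_degree_sample()
  fit <- fit_powerlaw(x)
  expect_s3_class(fit, "powerlaw_fit")
  expect_equal(unname(coef(fit)), c(fit$alpha, 2))
  expect_output(print(fit), "alpha = 2.92, xmin = 2")
  expect_output(print(summary(fit)), "CCDF")

  tab <- ccdf_table(fit)
  expect_equal(tab$empirical[1L], 1)
  expect_true(is.na(tab$fitted[tab$x < 2][1L]))
  expect_equal(tab$fitted[tab$x == 2], fit$n_tail / fit$n)

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))

  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(34L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 5))

  fitb <- fit_powerlaw(x, n_boot = 30, seed = 7)
  expect_false(is.na(fitb$p_value))
  expect_output(print(fitb), "bootstrap p")

  fixed <- fit_powerlaw(x, xmin = 3)
  expect_equal(fixed$xmin, 3)
  expect_equal(fixed$n_tail, 8L)
})
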