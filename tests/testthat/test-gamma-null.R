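test_that("pi, location and scale estimators follow their closed forms", {
  expect_equal(estimate_pi(0, 1e6), 1)
  expect_equal(estimate_pi(1e6, 1e6), 0.5)
  expect_equal(estimate_pi(2e6, 1e6), 1 / 3)
  expect_equal(estimate_location(c(8.1, 7.9, 9.3)), 7.9)
  expect_equal(estimate_location(3.2), 3.2)
  expect_error(estimate_location(numeric(0)), "empty")
  expect_equal(estimate_scale(c(2, 2, 2), 0, 1), 2)
  expect_equal(estimate_scale(c(3, 3), 0, 2), 1.5)
})

test_that("shape estimation: frozen starting value and fixed-point contract", {
  v <- c(1, 2, 4)
  s <- log(7 / 3) - (log(1) + log(2) + log(4)) / 3
  expect_equal(s, 0.1541507, tolerance = 1e-6)
  guess <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  expect_equal(guess, 3.3953, tolerance = 1e-4)
  k <- estimate_shape(v, y0 = 0, tol = 1e-8)
  expect_lt(abs(log(k) - digamma(k) - s), 1e-7)   # fixed point reached
  # independent oracle: profile likelihood maximised over a k grid
  loglik <- function(kk)
    sum(stats::dgamma(v, shape = kk, scale = mean(v) / kk, log = TRUE))
  k_grid <- stats::optimize(loglik, c(0.01, 50), maximum = TRUE,
                            tol = 1e-9)$maximum
  expect_equal(k, k_grid, tolerance = 1e-5)
  expect_error(estimate_shape(c(2, 2, 2), 0), "zero-variance")
})

test_that("shape estimation is consistent on exponential samples", {
  set.seed(4)
  v <- stats::rexp(1e5, rate = 1)
  expect_lt(abs(estimate_shape(v, 0) - 1), 0.05)
})

test_that("scale recovery on a shifted gamma sample", {
  set.seed(5)
  v <- 7.742 + stats::rgamma(1e5, shape = 1, scale = 1.9)
  y0 <- estimate_location(v)
  expect_lt(abs(y0 - 7.742), 0.05)
  k <- estimate_shape(v, y0)
  theta <- estimate_scale(v, y0, k)
  expect_lt(abs(theta - 1.9) / 1.9, 0.03)
})

test_that("sample_tail keeps the top decile and counts zeros", {
  flip <- local({ state <- FALSE; function(r) {
    state <<- !state; if (state) 5.0 else 0 } })
  smp <- sample_tail(flip, m = 1e6, n = 0, S = 200)
  expect_s3_class(smp, "tail_sample")
  expect_true(all(smp$v == 5.0))
  expect_equal(length(smp$v), 20)
  expect_equal(estimate_pi(smp$z, smp$S), 0.5, tolerance = 0.15)
  # retained boundary is the empirical 90th percentile of the positives
  set.seed(6)
  src <- function(r) 7 + stats::rgamma(1, 2, scale = 1.5)
  all_vals <- { set.seed(99); replicate(2000, src(0)) }
  set.seed(99)
  smp2 <- sample_tail(src, m = 1e7, n = 0, S = 2000)
  expect_equal(min(smp2$v), stats::quantile(all_vals, 0.9, names = FALSE),
               tolerance = 0.05)
  # zero-heavy sources still terminate thanks to replacement
  set.seed(7)
  rare <- function(r) if (stats::runif(1) < 0.05) stats::rexp(1) else 0
  expect_equal(length(sample_tail(rare, 1e6, 0, S = 100, tail_fraction = 1)$v),
               100)
  # an all-zero source errors out
  expect_error(sample_tail(function(r) 0, 1e6, 0, S = 100,
                           max_draw_factor = 5),
               "degenerate null")
})

test_that("S is auto-capped on small panels", {
  src <- function(r) stats::rexp(1) + 1
  set.seed(8)
  smp <- sample_tail(src, m = 600, n = 100, S = 1e6, tail_fraction = 0.5)
  expect_equal(smp$S, 500)
  expect_equal(length(smp$v), 250)
})

test_that("cdf_tail_max obeys its closed forms and monotonicity", {
  fit <- structure(list(pi = 1, y0 = 7, k = 1, theta = 1, q = 5),
                   class = "gamma_tail_fit")
  expect_equal(cdf_tail_max(7, fit), 0)
  fit$q <- 0
  expect_equal(cdf_tail_max(123.4, fit), 1)
  # exponential closed form: (1 - exp(-z))^q
  fit2 <- structure(list(pi = 1, y0 = 0, k = 1, theta = 1, q = 2),
                    class = "gamma_tail_fit")
  expect_equal(cdf_tail_max(log(2), fit2), 0.25, tolerance = 1e-12)
  # power property and monotonicity on a generic fit
  fit3 <- structure(list(pi = 0.4, y0 = 7.7, k = 1.3, theta = 1.9, q = 37.5),
                    class = "gamma_tail_fit")
  z <- seq(7, 40, length.out = 200)
  fit3_q1 <- fit3; fit3_q1$q <- 1
  expect_equal(cdf_tail_max(z, fit3), cdf_tail_max(z, fit3_q1)^37.5,
               tolerance = 1e-12)
  expect_true(all(diff(cdf_tail_max(z, fit3)) >= 0))
  expect_equal(cdf_tail_max(1e6, fit3), 1)
})

test_that("sample_max inverts the exponential closed form and brackets F", {
  fit <- structure(list(pi = 1, y0 = 7, k = 1, theta = 2, q = 1),
                   class = "gamma_tail_fit")
  M <- sample_max(fit, u = 0.5)
  expect_equal(M, 7 + 2 * log(2), tolerance = 1e-5)
  # bisection contract on an arbitrary fit, including a low initial guess
  fit2 <- structure(list(pi = 0.3, y0 = 7.7, k = 1.05, theta = 1.9, q = 800),
                    class = "gamma_tail_fit")
  set.seed(9)
  for (u in stats::runif(20)) {
    M <- sample_max(fit2, initial_guess = 10, precision = 1e-7, u = u)
    expect_lte(cdf_tail_max(M - 1e-5, fit2), u + 1e-9)
    expect_gte(cdf_tail_max(M + 1e-5, fit2), u - 1e-9)
  }
})

test_that("sampled maxima match explicit maxima of q gamma draws", {
  set.seed(10)
  q <- 40; k <- 1.2; theta <- 2; y0 <- 7.5
  fit <- structure(list(pi = 1, y0 = y0, k = k, theta = theta, q = q),
                   class = "gamma_tail_fit")
  M_samp <- replicate(4000, sample_max(fit, precision = 1e-6))
  M_expl <- replicate(4000, max(y0 + stats::rgamma(q, k, scale = theta)))
  expect_gt(suppressWarnings(stats::ks.test(M_samp, M_expl))$p.value, 0.01)
})

test_that("fit_tail recovers mixture parameters and sets q", {
  set.seed(11)
  src <- function(r)
    if (stats::runif(1) < 0.35) 7.7 + stats::rgamma(1, 1.0, scale = 1.9) else 0
  smp <- sample_tail(src, m = 2e6, n = 1000, S = 2e4, tail_fraction = 1.0)
  fit <- fit_tail(smp, m = 2e6, n = 1000)
  expect_lt(abs(fit$pi - 0.35) / 0.35, 0.10)
  expect_lt(abs(fit$y0 - 7.7) / 7.7, 0.05)
  expect_lt(abs(fit$k - 1.0), 0.10)
  expect_lt(abs(fit$theta - 1.9) / 1.9, 0.10)
  expect_equal(fit$q, (2e6 - 1000) * fit$pi * 1.0)
  # m = n means an empty remainder: q = 0 and the sampled max is 0
  fit0 <- fit; fit0$q <- 0
  expect_equal(sample_max(fit0), 0)
})

test_that("tail-fit recovery error shrinks as S grows", {
  set.seed(12)
  rel_err <- sapply(c(1e3, 1e4, 1e5), function(S) {
    v <- 7.7 + stats::rgamma(S, 1.0, scale = 1.9)
    smp <- structure(
      list(v = sort(v), z = round(S * 0.65 / 0.35), S = S, tail_fraction = 1),
      class = "tail_sample")
    fit <- fit_tail(smp, m = S + 1000, n = 1000)
    max(abs(fit$k - 1), abs(fit$theta - 1.9) / 1.9, abs(fit$y0 - 7.7) / 7.7)
  })
  expect_true(rel_err[3] < rel_err[1])
  expect_lt(rel_err[3], 0.05)
})
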