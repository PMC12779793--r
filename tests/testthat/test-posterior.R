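test_that("conjugate update gives Beta(x + 1/2, n - x + 1/2) under Jeffreys", {
  cases <- list(list(10, 8, 8.5, 2.5),
                list(1, 0, 0.5, 1.5),
                list(5, 5, 5.5, 0.5))
  for (cs in cases) {
    post <- mastery_posterior(cs[[1]], cs[[2]])
    expect_equal(post$alpha, cs[[3]])
    expect_equal(post$beta, cs[[4]])
    expect_equal(post$alpha + post$beta, cs[[1]] + 1)
  }
  post <- mastery_posterior(10, 8, "uniform")
  expect_equal(c(post$alpha, post$beta), c(9, 3))
})

test_that("invalid counts and priors are rejected with the violated bound", {
  expect_error(mastery_posterior(0, 0), "n")
  expect_error(mastery_posterior(5, -1), "x >= 0")
  expect_error(mastery_posterior(5, 6), "x <= n")
  expect_error(mastery_posterior(5.5, 2), "integer")
  expect_error(mastery_prior(c(0, 1)), "positive")
  expect_error(mastery_prior(c(-1, 1)), "positive")
})

test_that("mastery_prob reproduces the printed tail probabilities", {
  expect_equal(round(mastery_prob(mastery_posterior(10, 8), 0.90), 3), 0.143)
  expect_equal(round(mastery_prob(mastery_posterior(5, 5), 0.90), 2), 0.71)
  # frozen from the trapezoid oracle on Beta(4.5, 0.5)
  expect_equal(mastery_prob(mastery_posterior(4, 4), 0.90), 0.6565636,
               tolerance = 1e-6)
})

test_that("mastery_prob endpoints follow the continuous-posterior convention", {
  for (post in list(mastery_posterior(10, 8), mastery_posterior(5, 5),
                    mastery_posterior(3, 0))) {
    expect_identical(mastery_prob(post, 0), 1)
    expect_identical(mastery_prob(post, 1), 0)
  }
  expect_error(mastery_prob(mastery_posterior(5, 3), 1.1), "\\[0, 1\\]")
  expect_error(mastery_prob(mastery_posterior(5, 3), -0.1), "\\[0, 1\\]")
})

test_that("mastery_prob is non-increasing and continuous in the threshold", {
  post <- mastery_posterior(10, 8)
  ps <- seq(0, 1, length.out = 401)
  b <- mastery_prob(post, ps)
  expect_true(all(diff(b) <= 0))
  expect_true(max(abs(diff(b))) < 0.05)  # no jumps on a fine grid
})

test_that("lower_credible_bound reproduces the printed report bounds", {
  post <- mastery_posterior(10, 8)
  expect_equal(round(lower_credible_bound(post, 0.05), 4), 0.5475)
  expect_equal(round(lower_credible_bound(post, 0.10), 4), 0.6052)
  # bound shrinks to the lower support endpoint as the tail level vanishes
  as <- c(0.05, 1e-3, 1e-6, 1e-9)
  qs <- vapply(as, function(a) lower_credible_bound(post, a), numeric(1))
  expect_true(all(diff(qs) < 0))
  expect_lt(lower_credible_bound(mastery_posterior(1, 0), 1e-12), 1e-3)
  expect_error(lower_credible_bound(post, 0), "\\(0, 1\\)")
  expect_error(lower_credible_bound(post, 1), "\\(0, 1\\)")
})

test_that("posterior mean is the closed form (x + 1/2) / (n + 1)", {
  expect_identical(mean(mastery_posterior(10, 8)), 8.5 / 11)
  expect_equal(round(100 * mean(mastery_posterior(10, 8)), 2), 77.27)
  expect_equal(round(100 * mean(mastery_posterior(10, 9))), 86)
  expect_identical(mean(mastery_posterior(2, 1)), 0.5)
  for (n in c(3, 7, 12)) for (x in c(0, 2)) {
    expect_identical(mean(mastery_posterior(n, x)), (x + 0.5) / (n + 1))
  }
})

test_that("quantile/tail consistency: Pr(p >= q_a) = 1 - a", {
  for (n in c(2, 5, 10, 17)) for (x in 0:n) for (a in c(0.05, 0.1, 0.5)) {
    post <- mastery_posterior(n, x)
    expect_equal(mastery_prob(post, lower_credible_bound(post, a)), 1 - a,
                 tolerance = 1e-9)
  }
})

test_that("density grid is symmetric for symmetric posteriors", {
  post <- mastery_posterior(2, 1)  # Beta(1.5, 1.5)
  d <- density(post, 1001)
  expect_equal(d$density, rev(d$density), tolerance = 1e-12)
  expect_true(all(d$density >= 0))
})

test_that("density grid mode matches the closed-form beta mode", {
  d <- density(mastery_posterior(10, 9), 4097)
  expect_equal(d$mastery[which.max(d$density)], 8.5 / 9, tolerance = 1e-3)
})

test_that("density grid integrates to 1 for interior-mode posteriors", {
  for (post in list(mastery_posterior(10, 8), mastery_posterior(10, 9),
                    mastery_posterior(5, 3))) {
    d <- density(post, 4097)
    expect_equal(trapz(d$mastery, d$density), 1, tolerance = 1e-3)
  }
  expect_error(density(mastery_posterior(5, 3), 1), "npoints")
})

test_that("mastery_summary bundles the three component quantities", {
  s <- mastery_summary(10, 8, p_star = 0.90, a = 0.05)
  post <- mastery_posterior(10, 8)
  expect_identical(s$b, mastery_prob(post, 0.90))
  expect_identical(s$lower_bound, lower_credible_bound(post, 0.05))
  expect_identical(s$mean, mean(post))
  expect_equal(round(s$b, 3), 0.143)
  expect_equal(round(100 * s$lower_bound, 2), 54.75)
  expect_equal(round(100 * s$mean, 2), 77.27)
  s2 <- mastery_summary(10, 8, p_star = 0.80, a = 0.10)
  expect_equal(round(s2$b, 4), 0.4665)
  expect_equal(round(100 * s2$lower_bound, 2), 60.52)
  expect_identical(mastery_summary(10, 8, p_star = 1)$b, 0)
})

test_that("criterion_table reproduces the printed reference tables", {
  for (pk in names(golden_b_tables)) {
    p_star <- if (pk == "p90") 0.90 else 0.70
    for (nk in names(golden_b_tables[[pk]])) {
      tab <- criterion_table(as.integer(nk), p_star = p_star)
      expect_lte(max(abs(tab$b - golden_b_tables[[pk]][[nk]])), 0.005)
      expect_equal(tab$x, 0:as.integer(nk))
      expect_equal(tab$tau, (0:as.integer(nk)) / as.integer(nk))
    }
  }
})

test_that("criterion_table columns increase strictly with the correct count", {
  for (n in c(5, 8, 10, 15)) {
    tab <- criterion_table(n, p_star = 0.9, a = 0.05)
    expect_true(all(diff(tab$b) > 0))
    expect_true(all(diff(tab$lower_bound) > 0))
    expect_true(all(diff(tab$mean) > 0))
  }
})

test_that("criterion_table degenerates correctly at p_star = 0", {
  tab <- criterion_table(1, p_star = 0)
  expect_identical(tab$b, c(1, 1))
})

test_that("tail probabilities and quantiles match the numeric oracle", {
  # spot-check here; the full n <= 20 sweep runs in the acceptance tests
  ps <- seq(0.1, 0.9, by = 0.1)
  for (cs in list(c(5, 5), c(10, 0), c(10, 8), c(12, 6))) {
    post <- mastery_posterior(cs[[1]], cs[[2]])
    o <- beta_cdf_oracle(post$alpha, post$beta)
    expect_equal(mastery_prob(post, ps), oracle_tail_prob(o, ps),
                 tolerance = 1e-6)
    expect_equal(vapply(ps, function(a) lower_credible_bound(post, a),
                        numeric(1)),
                 oracle_quantile(o, ps), tolerance = 1e-6)
  }
})

test_that("posterior predictive proportion equals the mean, any horizon", {
  post <- mastery_posterior(10, 9)
  for (m in c(1, 10, 100)) {
    pr <- predict(post, m = m)
    expect_identical(pr$proportion, mean(post))
    expect_identical(pr$m, as.integer(m))
  }
  expect_error(predict(post, m = 0), "m")
})
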