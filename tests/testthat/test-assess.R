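test_that("posterior_ges reproduces two-state Bayes", {
  expect_equal(posterior_ges(c(0.5, 0.5), 0.45), 0.45)
  expect_equal(posterior_ges(rep(0.5, 7), 0.5), 0.5)
  expect_equal(posterior_ges(c(0.9, 0.2), 0.5), 0.18 / (0.18 + 0.08))
  expect_equal(posterior_ges(numeric(0), 0.3), 0.3)  # no evidence

  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    prior <- runif(1, 0.05, 0.95)
    expect_equal(posterior_ges(p, prior), oracle_posterior(p, prior),
                 tolerance = 1e-12)
  }
})

test_that("posterior_ges rejects bad priors and probabilities", {
  expect_error(posterior_ges(0.5, 0), "inside \\(0, 1\\)")
  expect_error(posterior_ges(0.5, 1), "inside \\(0, 1\\)")
  expect_error(posterior_ges(1.2, 0.5), "\\[0, 1\\]")
  expect_equal(posterior_ges(c(1, 0.5), 0.5), 1)  # certain pass
  expect_equal(posterior_ges(c(0, 0.5), 0.5), 0)  # certain fail
  expect_warning(out <- posterior_ges(c(0, 1), 0.5), "contradictory")
  expect_true(is.nan(out))
})

test_that("posterior_ges is monotone, permutation-invariant and ignores p=0.5", {
  set.seed(12)
  for (i in 1:20) {
    p <- runif(5, 0.05, 0.95)
    prior <- runif(1, 0.1, 0.9)
    base <- posterior_ges(p, prior)
    # strictly increasing in each p_i
    for (j in 1:5) {
      up <- p; up[j] <- min(up[j] + 0.03, 0.999)
      expect_gt(posterior_ges(up, prior), base)
    }
    # strictly increasing in the prior
    expect_gt(posterior_ges(p, min(prior + 0.03, 0.99)), base)
    # permutation invariance (associativity of the likelihood product)
    expect_equal(posterior_ges(sample(p), prior), base, tolerance = 1e-14)
    # uninformative evidence leaves the posterior unchanged
    expect_equal(posterior_ges(c(p, 0.5), prior), base, tolerance = 1e-14)
  }
})

test_that("chaining identical evidence moves the posterior the right way", {
  p_up <- c(0.7, 0.6)
  post1 <- posterior_ges(p_up, 0.5)
  post2 <- posterior_ges(p_up, post1)
  expect_gt(post1, 0.5)
  expect_gt(post2, post1)

  flat <- posterior_ges(c(0.5, 0.5), 0.37)
  expect_equal(posterior_ges(c(0.5, 0.5), flat), flat)
})

test_that("ges_assess chains posteriors through the common years", {
  a <- series_at_target("A", 2007:2008, target = 1, sd = 0.1)
  b <- series_at_target("B", 2007:2008, target = 2, sd = 0.2)
  suppressMessages(fit <- ges_assess(indicator_set(a, b), prior0 = 0.45))
  expect_equal(fit$posterior, c(0.45, 0.45))
  expect_equal(fit$prior_chain, c(0.45, 0.45))
  expect_equal(unname(fit$likelihoods), matrix(0.5, 2, 2))

  # prior chaining invariant
  up <- indicator_set(series_with_p("U", 2001:2005, rep(0.8, 5)),
                      series_with_p("V", 2001:2005, rep(0.7, 5)))
  fit2 <- ges_assess(up, prior0 = 0.5)
  expect_equal(fit2$prior_chain[-1], fit2$posterior[-length(fit2$posterior)])
  expect_true(all(diff(fit2$posterior) > 0))

  # single indicator with near-certain evidence drives the posterior to 1
  sure <- indicator_set(series_with_p("S", 2001:2006, rep(1 - 1e-6, 6)))
  fit3 <- ges_assess(sure, prior0 = 0.5)
  expect_true(all(diff(fit3$posterior) >= 0))   # saturates at machine 1
  expect_gt(fit3$posterior[2], fit3$posterior[1])
  expect_gt(tail(fit3$posterior, 1), 0.999)
})

test_that("the prior-chain discount shrinks memory toward indifference", {
  set_ <- indicator_set(series_with_p("U", 2001:2006, rep(0.9, 6)))
  full <- ges_assess(set_, prior0 = 0.5, lambda = 1)
  half <- ges_assess(set_, prior0 = 0.5, lambda = 0.5)
  expect_true(all(half$posterior[-1] < full$posterior[-1]))
  expect_equal(half$prior_chain[2], 0.5 * full$posterior[1] + 0.25,
               tolerance = 1e-12)
})

test_that("union assessment treats a missing indicator as no evidence", {
  a <- series_with_p("A", 2001:2004, rep(0.8, 4))
  b <- series_with_p("B", 2002:2004, rep(0.8, 3))  # misses 2001
  both <- indicator_set(a, b)
  fit_union <- ges_assess(both, years = "union")
  expect_identical(fit_union$times, 2001:2004)
  expect_true(is.na(fit_union$likelihoods["2001", "B"]))
  # year 2001 posterior equals the single-indicator update
  expect_equal(fit_union$posterior[1], posterior_ges(0.8, 0.5))
  fit_common <- ges_assess(both)
  expect_identical(fit_common$times, 2002:2004)
})

test_that("ges_assess names the offending indicator on failure", {
  a <- series_at_target("A", 2001:2003)
  b <- indicator_series("B", 2001:2003, 1:3, 0.1)  # no target
  expect_error(ges_assess(indicator_set(a, b)), "B")
  expect_error(ges_assess(indicator_set(a), prior0 = 1.2), "prior0")
})

test_that("early warnings flag persistent low or high scorers", {
  low <- series_with_p("LOW", 2001:2003, rep(0.1, 3))
  ok <- series_with_p("OK", 2001:2003, rep(0.5, 3))
  fit <- ges_assess(indicator_set(low, ok))
  w <- early_warning(fit, threshold = 0.25, k = 3)
  expect_identical(nrow(w), 1L)
  expect_identical(w$indicator, "LOW")
  expect_identical(w$side, "low")
  expect_identical(c(w$from, w$to, w$length), c(2001L, 2003L, 3L))

  # runs of length 1 do not qualify
  blip <- series_with_p("BLIP", 2001:2003, c(0.1, 0.6, 0.1))
  fit2 <- ges_assess(indicator_set(blip, series_with_p("OK", 2001:2003,
                                                       rep(0.5, 3))))
  expect_identical(nrow(early_warning(fit2, k = 2)), 0L)

  # high-side runs are symmetric
  hi <- series_with_p("HI", 2001:2004, rep(0.9, 4))
  fit3 <- ges_assess(indicator_set(hi, series_with_p("OK", 2001:2004,
                                                     rep(0.5, 4))))
  w3 <- early_warning(fit3, k = 3)
  expect_identical(w3$side, "high")
  expect_identical(w3$length, 4L)

  expect_message(w4 <- early_warning(fit3, k = 10), "exceeds")
  expect_identical(nrow(w4), 0L)
})

test_that("assessment methods print and summarise coherently", {
  fit <- ges_assess(indicator_set(series_with_p("A", 2001:2004,
                                                c(0.6, 0.7, 0.8, 0.9))))
  df <- as.data.frame(fit)
  expect_identical(names(df), c("year", "prior", "posterior"))
  expect_output(print(fit), "P\\(GES\\)")
  expect_output(print(summary(fit)), "Sequential Bayesian GES assessment")
})
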