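test_that("model_spec infers families and validates pairing", {
  expect_identical(model_spec("chunks")$family, "poisson")
  expect_identical(model_spec("max_nesting")$family, "poisson")
  expect_identical(model_spec("entropy")$family, "zib")
  expect_identical(model_spec("tnt_ratio")$family, "zib")
  expect_error(model_spec("mystery"), "cannot infer")
})

test_that("Poisson intercept-only posterior matches the closed form", {
  d <- data.frame(chunks = c(5, 6, 7), group = "g")
  fit <- fit_group_model(d, model_spec("chunks", reference = "g", seed = 42))
  # flat prior on the log-scale intercept => posterior of the rate is
  # Gamma(sum y, n); exact posterior mean of the intercept is
  # digamma(18) - log(3) = 1.7646, within 0.028 of log(6) = 1.7918
  expect_lt(abs(fit$mean[1] - (digamma(18) - log(3))), 0.02)
  expect_lt(abs(fit$mean[1] - log(6)), 0.05)
  expect_true(fit$ci_low[1] <= fit$mean[1] && fit$mean[1] <= fit$ci_high[1])

  # MLE route hits log(6) exactly
  mle <- fit_group_model(d, model_spec("chunks", reference = "g"),
                         method = "mle")
  expect_equal(mle$mean[1], log(6), tolerance = 1e-4)
})

test_that("flat-prior Poisson posterior mean converges to log sample mean", {
  set.seed(10)
  d <- data.frame(chunks = rpois(10000, 5.5), group = "g")
  fit <- fit_group_model(d, model_spec("chunks", reference = "g",
                                       chains = 2, iter = 1000,
                                       warmup = 500, seed = 3))
  expect_equal(fit$mean[1], log(mean(d$chunks)), tolerance = 0.01)
})

test_that("treatment coding: reference fitted mean is exp(intercept)", {
  set.seed(4)
  d <- data.frame(
    chunks = c(rpois(200, 6), rpois(200, 3)),
    group = rep(c("chimpanzee", "markov"), each = 200))
  fit <- fit_group_model(d, model_spec("chunks", seed = 9))
  ref_mean <- mean(d$chunks[d$group == "chimpanzee"])
  expect_equal(exp(fit$mean[fit$term == "chimpanzee"]), ref_mean,
               tolerance = 0.01 * ref_mean + 3 * sqrt(ref_mean / 200))
  expect_identical(fit$role[fit$term == "markov"], "contrast")
  # contrast recovers the log rate ratio
  expect_equal(fit$mean[fit$term == "markov"], log(3 / 6), tolerance = 0.15)
})

test_that("zero-inflated beta handles the all-zero degenerate case", {
  d <- data.frame(entropy = rep(0, 30), group = "g")
  # beta parameters are unidentified when no positive values exist, so the
  # convergence flag is expected; only the zero-inflation mass is of interest
  fit <- suppressWarnings(
    fit_group_model(d, model_spec("entropy", reference = "g",
                                  chains = 2, iter = 800,
                                  warmup = 400, seed = 5)))
  zi <- plogis(fit$mean[fit$term == "zi_logit"])
  expect_gt(zi, 0.85)
})

test_that("zero-inflated beta recovers two-group structure", {
  set.seed(6)
  n <- 300
  y <- c(rbeta(n, 8, 2), rbeta(n, 2, 8))
  zero <- runif(2 * n) < 0.15
  y[zero] <- 0
  d <- data.frame(entropy = y, group = rep(c("chimpanzee", "markov"), each = n))
  fit <- fit_group_model(d, model_spec("entropy", seed = 12))
  a <- fit$mean[fit$term == "chimpanzee"]
  b <- fit$mean[fit$term == "markov"]
  expect_lt(abs(a - qlogis(0.8)), 0.2)
  expect_lt(abs(b - (qlogis(0.2) - qlogis(0.8))), 0.3)
  zi <- plogis(fit$mean[fit$term == "zi_logit"])
  expect_lt(abs(zi - 0.15), 0.05)
})

test_that("input validation: family bounds and group sizes", {
  expect_error(
    fit_group_model(data.frame(entropy = c(0.2, 1.0, 0.3), group = "g"),
                    model_spec("entropy", reference = "g")),
    "\\[0, 1\\)")
  expect_error(
    fit_group_model(data.frame(chunks = c(1, 2, 3), group = c("a", "a", "b")),
                    model_spec("chunks")),
    "at least 2")
  expect_error(
    fit_group_model(data.frame(chunks = c(0.5, 1.2), group = "g"),
                    model_spec("chunks", reference = "g")),
    "integer")
})

test_that("compare_report flags contrasts whose interval excludes zero", {
  est <- structure(data.frame(
    outcome = "chunks",
    term = c("chimpanzee", "random", "markov"),
    role = c("intercept", "contrast", "contrast"),
    mean = c(1.76, -0.22, -0.01),
    ci_low = c(1.68, -0.33, -0.12),
    ci_high = c(1.84, -0.10, 0.10),
    rhat = NA_real_, method = "mcmc", stringsAsFactors = FALSE),
    class = c("model_estimates", "data.frame"))
  rep <- compare_report(est)
  expect_identical(rep$differs[rep$term == "random"], TRUE)
  expect_identical(rep$differs[rep$term == "markov"], FALSE)
  expect_true(is.na(rep$differs[rep$term == "chimpanzee"]))

  # boundary exactly at zero is not exclusion
  est$ci_low[3] <- 0; est$ci_high[3] <- 0; est$mean[3] <- 0
  expect_identical(compare_report(est)$differs[3], FALSE)
})

test_that("intercept recovery: nominal coverage at n = 140 (10 replicates)", {
  hit <- 0
  for (r in 1:10) {
    set.seed(100 + r)
    d <- data.frame(chunks = rpois(140, exp(1.76)), group = "g")
    fit <- fit_group_model(d, model_spec("chunks", reference = "g",
                                         chains = 2, iter = 1200,
                                         warmup = 600, seed = 200 + r))
    if (fit$ci_low[1] <= 1.76 && 1.76 <= fit$ci_high[1]) hit <- hit + 1
  }
  expect_gte(hit, 8)
})
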