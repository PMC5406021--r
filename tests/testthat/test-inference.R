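# ABC machinery: rejection, logistic scenario posteriors, local-linear
# adjustment and the PCA model check, mostly on small constructed tables.

# a tiny reference table built around a toy simulation so downstream
# functions see the real object shape
build_small_rt <- function(n = 300, seed = 51) {
  set.seed(seed)
  build_reference_table(toy_split_scenarios(), n, panel = toy_panel(),
                        include_seq = FALSE)
}

test_that("rejection keeps the closest rows under MAD normalization", {
  rt <- build_small_rt(100)
  obs <- list(stats = rt$stats[7, ], mask = rt$mask[7, ])
  ret <- rejection_sample(rt, obs, tolerance = 0.05)
  # the row identical to the observation comes first at distance 0
  expect_equal(ret$idx[1], 7)
  expect_equal(ret$dist[1], 0)
  # retained set equals a brute-force sort of all distances
  scales <- invabc:::.mad_scales(rt$stats, rt$mask)
  use <- !is.na(scales) & !obs$mask
  z <- sweep(sweep(rt$stats[, use, drop = FALSE], 2, obs$stats[use], `-`),
             2, scales[use], `/`)
  d <- sqrt(rowSums(z^2))
  expect_equal(sort(ret$idx), sort(order(d)[seq_len(ceiling(0.05 * 300))]))
  # tolerance 1 retains everything
  expect_equal(length(rejection_sample(rt, obs, 1)$idx), 300)
  expect_warning(rejection_sample(rt, obs, 1e-4), "retained")
})

test_that("posterior probabilities are invariant to statistic rescaling", {
  rt <- build_small_rt(200)
  obs <- list(stats = colMeans(rt$stats), mask = rt$mask[1, ] & FALSE)
  names(obs$stats) <- colnames(rt$stats)
  p1 <- logistic_scenario_posterior(rejection_sample(rt, obs, 0.1))
  rt2 <- rt
  rt2$stats[, 1] <- rt2$stats[, 1] * 1000 + 5   # affine rescale one stat
  obs2 <- obs; obs2$stats[1] <- obs2$stats[1] * 1000 + 5
  p2 <- logistic_scenario_posterior(rejection_sample(rt2, obs2, 0.1))
  expect_equal(p1$prob, p2$prob, tolerance = 1e-6)
})

test_that("logistic posterior finds signal and returns flat nulls", {
  set.seed(52)
  # constructed table: scenario 2 separable along one statistic
  n <- 400
  stats <- cbind(s1 = c(rnorm(n, 0), rnorm(n, 3)), s2 = rnorm(2 * n))
  rt <- list(scenario = rep(1:2, each = n), stats = stats,
             mask = matrix(FALSE, 2 * n, 2,
                           dimnames = list(NULL, colnames(stats))),
             params = list(matrix(0, n, 1), matrix(0, n, 1)),
             scenarios = list(a = NULL, b = NULL))
  class(rt) <- "reference_table"
  obs_near_2 <- list(stats = c(s1 = 3, s2 = 0),
                     mask = c(s1 = FALSE, s2 = FALSE))
  post <- logistic_scenario_posterior(
    rejection_sample(rt, obs_near_2, 0.5))
  expect_equal(attr(post, "chosen"), "2")
  expect_gt(post$prob[post$scenario == "2"], 0.8)
  expect_equal(sum(post$prob), 1, tolerance = 1e-9)
  expect_true(all(post$lo <= post$prob & post$prob <= post$hi))
  # no signal at all: probabilities near the uniform prior
  stats0 <- cbind(s1 = rnorm(2 * n), s2 = rnorm(2 * n))
  rt0 <- rt; rt0$stats <- stats0
  dimnames(rt0$mask) <- list(NULL, colnames(stats0))
  obs0 <- list(stats = c(s1 = 0, s2 = 0), mask = c(s1 = FALSE, s2 = FALSE))
  post0 <- logistic_scenario_posterior(rejection_sample(rt0, obs0, 0.5))
  expect_true(all(abs(post0$prob - 0.5) < 0.12))
})

test_that("two-scenario logistic coefficients match a glm IRLS fit", {
  set.seed(53)
  n <- 250
  stats <- cbind(x = c(rnorm(n, -0.5), rnorm(n, 0.5)),
                 y = rnorm(2 * n))
  rt <- list(scenario = rep(1:2, each = n), stats = stats,
             mask = matrix(FALSE, 2 * n, 2,
                           dimnames = list(NULL, colnames(stats))),
             params = list(matrix(0, n, 1), matrix(0, n, 1)),
             scenarios = list(a = NULL, b = NULL))
  class(rt) <- "reference_table"
  obs <- list(stats = c(x = 0, y = 0), mask = c(x = FALSE, y = FALSE))
  ret <- rejection_sample(rt, obs, 1)
  post <- logistic_scenario_posterior(ret)
  fit <- glm(I(ret$scenario == 2) ~ ret$z, family = binomial())
  p_glm <- 1 / (1 + exp(-unname(coef(fit)[1])))
  expect_equal(post$prob[post$scenario == "2"], p_glm, tolerance = 1e-4)
})

test_that("local-linear adjustment collapses a noiseless linear toy", {
  set.seed(54)
  n <- 400
  theta <- runif(n, 10, 20)
  stats <- cbind(a = 2 * theta + 1, b = -theta + 3)  # deterministic map
  rt <- list(scenario = rep(1L, n), stats = stats,
             mask = matrix(FALSE, n, 2,
                           dimnames = list(NULL, colnames(stats))),
             params = list(matrix(theta, ncol = 1,
                                  dimnames = list(NULL, "THETA"))),
             scenarios = list(a = NULL))
  class(rt) <- "reference_table"
  truth <- 14.2
  obs <- list(stats = c(a = 2 * truth + 1, b = -truth + 3),
              mask = c(a = FALSE, b = FALSE))
  ret <- rejection_sample(rt, obs, 0.5)
  adj <- local_linear_adjust(rt, ret, 1, transform = "none")
  expect_lt(max(abs(adj$draws[, "THETA"] - truth)), 1e-6)
  # log transform never produces negative adjusted values
  adj_log <- local_linear_adjust(rt, ret, 1, transform = "log")
  expect_true(all(adj_log$draws > 0))
  expect_error(local_linear_adjust(rt, ret, 1, min_retained = 1e6),
               "retained")
})

test_that("error-rate estimation is reproducible and counts choices", {
  rt <- build_small_rt(250)
  e1 <- confidence_error_rates(rt, n_pods = 3, tolerance = 0.05, seed = 5)
  e2 <- confidence_error_rates(rt, n_pods = 3, tolerance = 0.05, seed = 5)
  expect_identical(e1$choices, e2$choices)
  expect_equal(rowSums(e1$choices), rep(3, 3), ignore_attr = TRUE)
  expect_true(all(e1$rates$type1 >= 0 & e1$rates$type1 <= 1))
})

test_that("PCA model check centres the mean observation at the origin", {
  rt <- build_small_rt(200)
  obs <- list(stats = colMeans(rt$stats), mask = rt$mask[1, ] & FALSE)
  names(obs$stats) <- colnames(rt$stats)
  chk <- pca_model_check(rt, obs)
  expect_lt(max(abs(chk$observed_scores)), 1e-6)
  expect_lte(sum(chk$var_explained), 1 + 1e-9)
  expect_true(all(chk$observed_percentile >= 0 &
                    chk$observed_percentile <= 1))
  # posterior-predictive projection has matching dimensions
  chk2 <- pca_model_check(rt, obs, posterior_stats = rt$stats[1:20, ])
  expect_equal(dim(chk2$posterior_scores), c(20L, 3L))
})

test_that("reference tables are seed-reproducible row for row", {
  set.seed(77)
  rt1 <- build_reference_table(toy_split_scenarios()[1], 30,
                               panel = toy_panel(), include_seq = FALSE,
                               seed = 9)
  rt2 <- build_reference_table(toy_split_scenarios()[1], 30,
                               panel = toy_panel(), include_seq = FALSE,
                               seed = 9)
  expect_identical(rt1$stats, rt2$stats)
  expect_identical(rt1$params, rt2$params)
  expect_equal(nrow(rt1$stats), 30)
  # parameter rows satisfy the scenario's order conditions
  expect_true(all(rt1$params[[1]][, "TO"] > rt1$params[[1]][, "TR"]))
})
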