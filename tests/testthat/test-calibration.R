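test_that("zero residuals with unit sigma give the analytic likelihood", {
  zr <- zero_residual_problem(sigma_mode = "estimate")
  theta <- zr$theta
  theta[paste0("sigma_", c("sphinganine", "ceramide", "sphingosine"))] <- 1
  expect_equal(negative_log_likelihood(zr$problem, theta, engine = "r"),
               4 * log(2 * pi), tolerance = 1e-8)
  expect_equal(negative_log_likelihood(zr$problem, theta, engine = "cpp"),
               4 * log(2 * pi), tolerance = 1e-8)
  # doubling sigma with zero residuals adds n * log(2)
  theta2 <- theta
  theta2[paste0("sigma_", c("sphinganine", "ceramide", "sphingosine"))] <- 2
  expect_equal(negative_log_likelihood(zr$problem, theta2) -
                 negative_log_likelihood(zr$problem, theta),
               8 * log(2), tolerance = 1e-8)
})

test_that("both likelihood engines equal the naive summation oracle", {
  truth <- paper_like_truth("feedback")
  m <- generate_measurements(truth, synthetic_design(), seed = 3)
  problem <- make_problem(m, "feedback", sigma_mode = "estimate")
  set.seed(99)
  for (i in 1:5) {
    theta <- full_theta(problem)
    theta[rate_names()] <- exp(stats::runif(7, log(0.3), log(3)))
    theta["alpha_cer"] <- -stats::runif(1)
    theta[c("s_sphinganine", "s_ceramide", "s_sphingosine")] <-
      c(20, 300, 25) * exp(stats::runif(3, -0.3, 0.3))
    theta[c("sigma_sphinganine", "sigma_ceramide", "sigma_sphingosine")] <-
      c(0.8, 25, 1.2)
    theta["x0_s1p"] <- stats::runif(1, 0.05, 1)
    oracle <- naive_nll(problem, theta,
                        c(sphinganine = theta[["sigma_sphinganine"]],
                          ceramide = theta[["sigma_ceramide"]],
                          sphingosine = theta[["sigma_sphingosine"]]))
    expect_equal(negative_log_likelihood(problem, theta, engine = "r"),
                 oracle, tolerance = 1e-10)
    expect_equal(negative_log_likelihood(problem, theta, engine = "cpp"),
                 negative_log_likelihood(problem, theta, engine = "r"),
                 tolerance = 1e-10)
  }
})

test_that("the likelihood decomposes per measurement", {
  truth <- paper_like_truth("feedback")
  m <- generate_measurements(truth, synthetic_design(), seed = 4)
  problem <- make_problem(m, "feedback", sigma_mode = "estimate")
  theta <- truth_theta(truth, problem)
  theta[c("sigma_sphinganine", "sigma_ceramide", "sigma_sphingosine")] <-
    c(0.8, 25, 1.2)
  drop_row <- which(m$time_dpf == 4)[5]
  problem_minus <- make_problem(m[-drop_row, ], "feedback",
                                sigma_mode = "estimate")
  pred <- predict_observables(problem, theta)
  row <- m[drop_row, ]
  yhat <- pred$predicted[pred$observable_id == row$observable_id &
                           pred$condition_id == row$condition_id &
                           pred$time_dpf == row$time_dpf]
  s <- theta[[paste0("sigma_", row$observable_id)]]
  term <- 0.5 * log(2 * pi) + log(s) + (yhat - row$value)^2 / (2 * s^2)
  expect_equal(negative_log_likelihood(problem, theta) -
                 negative_log_likelihood(problem_minus, theta),
               term, tolerance = 1e-10)
})

test_that("2-dpf means divided by the scaling set the initial state", {
  m <- expand.grid(observable_id = c("sphinganine", "ceramide",
                                     "sphingosine"),
                   condition_id = c("wild_type", "mutant"),
                   time_dpf = 2, replicate = 1:2, stringsAsFactors = FALSE)
  m$value <- 10
  m$value[m$observable_id == "ceramide" &
            m$condition_id == "wild_type"] <- c(4, 6)
  problem <- make_problem(m, "no_feedback")
  theta <- full_theta(problem, c(s_ceramide = 2))
  x0 <- set_initial_from_data(problem, theta)
  expect_equal(x0$wild_type[["ceramide"]], 2.5)
  expect_equal(x0$wild_type[["s1p"]], theta[["x0_s1p"]])
  # with s = 1 the 2-dpf prediction equals the 2-dpf sample mean exactly
  pred <- predict_observables(problem, full_theta(problem), times_dpf = 2)
  expect_equal(pred$predicted[pred$observable_id == "ceramide" &
                                pred$condition_id == "wild_type"], 5)
  # rescaling s leaves the predicted observable at 2 dpf invariant
  theta10 <- full_theta(problem, c(s_ceramide = 10))
  x0_10 <- set_initial_from_data(problem, theta10)
  expect_equal(x0_10$wild_type[["ceramide"]], 0.5)
  pred10 <- predict_observables(problem, theta10, times_dpf = 2)
  expect_equal(pred10$predicted[pred10$observable_id == "ceramide" &
                                  pred10$condition_id == "wild_type"], 5)
})

test_that("sigma_mle is the root-mean-square residual and minimises the NLL", {
  expect_equal(sigma_mle(c(1, -1, 1, -1)), 1)
  expect_warning(s0 <- sigma_mle(c(0, 0, 0)), "degenerate")
  expect_equal(s0, 0)
  expect_error(sigma_mle(numeric(0)), "empty")
  expect_equal(sigma_mle(list(a = c(3, -3), b = c(1, 1))),
               c(a = 3, b = 1))
  set.seed(61)
  r <- stats::rnorm(40, 0, 2.5)
  nll_sigma <- function(s) sum(0.5 * log(2 * pi) + log(s) + r^2 / (2 * s^2))
  grid <- seq(0.5, 5, by = 0.001)
  expect_equal(grid[which.min(vapply(grid, nll_sigma, numeric(1)))],
               sigma_mle(r), tolerance = 1e-3)
})

test_that("student-t confidence intervals match the quantile oracle", {
  m <- data.frame(observable_id = "ceramide", condition_id = "wild_type",
                  time_dpf = 2, replicate = 1:4, value = c(1, 1, 1, 1))
  ci <- ci95(m)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
  m$value <- c(0, 2, 0, 2)
  m2 <- m[1:2, ]
  ci2 <- ci95(m2)
  hw <- stats::qt(0.975, 1) * stats::sd(c(0, 2)) / sqrt(2)
  expect_equal(ci2$mean, 1)
  expect_equal(ci2$ci_high - ci2$mean, hw, tolerance = 1e-10)
  expect_equal(round(hw, 4), 12.7062)
  # any method: the interval contains the sample mean
  cib <- ci95(m, method = "bootstrap", seed = 2)
  expect_true(all(cib$ci_low <= cib$mean & cib$mean <= cib$ci_high))
  expect_error(ci95(m[1, ]), ">= 2")
})

test_that("fitting is deterministic given the seed", {
  truth <- paper_like_truth("feedback")
  m <- generate_measurements(truth, synthetic_design(), seed = 8)
  problem <- make_problem(m, "feedback")
  f1 <- fit(problem, n_starts = 4, seed = 17)
  f2 <- fit(problem, n_starts = 4, seed = 17)
  expect_identical(f1, f2)
  expect_true(is.finite(f1$nll))
  tab <- problem$parameters
  free <- tab$parameter_id[tab$estimate]
  expect_true(all(f1$theta_hat[free] >= tab$lower[tab$estimate] &
                    f1$theta_hat[free] <= tab$upper[tab$estimate]))
})

test_that("the fit is at least as good as the truth on noise-free data", {
  truth <- paper_like_truth("feedback")
  truth$sigma[] <- 0
  m <- generate_measurements(truth, synthetic_design(), seed = 9)
  problem <- make_problem(m, "feedback")
  theta_true <- truth_theta(paper_like_truth("feedback"), problem)
  theta_true["x0_s1p"] <- 0.3
  f <- fit(problem, n_starts = 3, seed = 5,
           extra_starts = list(theta_true))
  expect_lte(f$nll,
             negative_log_likelihood(problem, theta_true) + 1e-6)
})

test_that("jointly estimated sigma matches the analytic profile", {
  truth <- paper_like_truth("feedback")
  m <- generate_measurements(truth, synthetic_design(), seed = 10)
  # profile-mode fit supplies a warm start; the joint fit must then place
  # its sigma at the analytic conditional optimum of its own residuals
  f0 <- fit(make_problem(m, "feedback"), n_starts = 8, seed = 2)
  problem <- make_problem(m, "feedback", sigma_mode = "estimate")
  warm <- full_theta(problem, f0$theta_hat)
  warm[paste0("sigma_", names(f0$sigma_hat))] <- f0$sigma_hat
  f <- fit(problem, n_starts = 2, seed = 2, extra_starts = list(warm),
           control = fit_control(maxit = 2000, factr = 1e3, ndeps = 1e-6))
  prof <- f$sigma_hat  # rms residuals at the optimum
  est <- f$theta_hat[paste0("sigma_", names(prof))]
  expect_equal(unname(est), unname(prof), tolerance = 1e-4)
})

test_that("rescaling one species and its scaling factor leaves the NLL invariant", {
  truth <- paper_like_truth("feedback")
  m <- generate_measurements(truth, synthetic_design(), seed = 12)
  problem <- make_problem(m, "feedback", sigma_mode = "estimate")
  theta <- truth_theta(truth, problem)
  theta[c("sigma_sphinganine", "sigma_ceramide", "sigma_sphingosine")] <-
    c(0.8, 25, 1.2)
  cfac <- 7.3
  m2 <- m
  sel <- m2$observable_id == "ceramide"
  m2$value[sel] <- m2$value[sel] * cfac
  problem2 <- make_problem(m2, "feedback", sigma_mode = "estimate")
  theta2 <- theta
  theta2["s_ceramide"] <- theta2["s_ceramide"] * cfac
  theta2["sigma_ceramide"] <- theta2["sigma_ceramide"] * cfac
  # residuals scale by c; with sigma scaled too the quadratic terms match
  expect_equal(negative_log_likelihood(problem2, theta2) -
                 negative_log_likelihood(problem, theta),
               16 * log(cfac), tolerance = 1e-8)
})

test_that("coverage assessment flags predictions outside the intervals", {
  truth <- paper_like_truth("feedback")
  m <- generate_measurements(truth, synthetic_design(), seed = 13)
  problem <- make_problem(m, "feedback")
  theta <- truth_theta(truth, problem)
  fake_fit <- structure(list(theta_hat = theta, nll = NA_real_,
                             variant = "feedback"),
                        class = "fit_result")
  ass <- assess_fit(fake_fit, problem)
  expect_true(all(ass$inside[ass$at_initial_condition]))
  ci <- ci95(problem$measurements)
  merged <- merge(ass, ci,
                  by = c("observable_id", "condition_id", "time_dpf"))
  manual <- merged$ci_low.x <= merged$predicted &
    merged$predicted <= merged$ci_high.x
  manual[merged$time_dpf == 2] <- TRUE
  expect_equal(merged$inside, manual)
  # force a prediction outside by corrupting the scaling
  theta_bad <- theta
  theta_bad["s_ceramide"] <- theta_bad["s_ceramide"] * 5
  fake_bad <- structure(list(theta_hat = theta_bad, nll = NA_real_,
                             variant = "feedback"),
                        class = "fit_result")
  ass_bad <- assess_fit(fake_bad, problem)
  expect_false(all(ass_bad$inside[ass_bad$observable_id == "ceramide" &
                                    ass_bad$time_dpf == 4]))
})

test_that("the feedback variant nests the no-feedback variant", {
  truth <- paper_like_truth("no_feedback")
  m <- generate_measurements(truth, synthetic_design(), seed = 14)
  rep <- compare_variants(m, seed = 14, n_starts = 6)
  expect_gte(rep$delta_nll, -1e-6)
  # on no-feedback truth the feedback model gains essentially nothing
  expect_lt(rep$delta_nll, 2)
})
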