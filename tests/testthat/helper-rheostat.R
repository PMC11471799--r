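# Shared fixtures, built in code.

# Random strictly reversible core parameter set (all rates positive).
draw_core_params <- function() {
  r <- function(lo = 0.2, hi = 5) exp(stats::runif(1, log(lo), log(hi)))
  core_parameters(k0 = r(), k1r = r(), k2f = r(), k2r = r(), k3 = r(),
                  k3r = r(), k4 = r())
}

irreversible_chain <- function(k0 = 1, k2f = 1, k3 = 1, k4 = 1) {
  core_parameters(k0 = k0, k1r = 0, k2f = k2f, k2r = 0, k3 = k3, k3r = 0,
                  k4 = k4)
}

truth_theta <- function(truth, problem) {
  full_theta(problem, c(unlist(unclass(truth$params)[rate_names()]),
                        alpha_hai1a = truth$params$alpha_hai1a,
                        alpha_cer = truth$params$alpha_cer,
                        stats::setNames(truth$scaling,
                                        paste0("s_", names(truth$scaling))),
                        x0_s1p = mean(c(truth$x0$wild_type[["s1p"]],
                                        truth$x0$mutant[["s1p"]]))))
}

rate_names <- function() c("k00", "k01", "k2f", "k2r", "k3", "k3r", "k4")

# A minimal problem with exactly 8 measurements and zero residuals at a
# reference theta: 2-dpf singletons for each observable/condition (6 rows)
# plus one 4-dpf ceramide value per condition, set to the model prediction.
zero_residual_problem <- function(sigma_mode = "estimate") {
  m2 <- expand.grid(observable_id = c("sphinganine", "ceramide",
                                      "sphingosine"),
                    condition_id = c("wild_type", "mutant"),
                    time_dpf = 2, replicate = 1L,
                    stringsAsFactors = FALSE)
  m2$value <- c(8, 300, 10, 6, 220, 7.5)
  m4 <- data.frame(observable_id = "ceramide",
                   condition_id = c("wild_type", "mutant"),
                   time_dpf = 4, replicate = 1L, value = 0)
  meas <- rbind(m2, m4)
  problem <- make_problem(meas, "feedback", sigma_mode = sigma_mode)
  theta <- full_theta(problem, c(k00 = 1, k01 = 2, k2f = 1, k2r = 0.5,
                                 k3 = 2, k3r = 0.1, k4 = 1,
                                 alpha_hai1a = 0.5, alpha_cer = -1,
                                 s_sphinganine = 20, s_ceramide = 300,
                                 s_sphingosine = 25, x0_s1p = 0.3))
  pred <- predict_observables(problem, theta, times_dpf = 4)
  for (i in which(meas$time_dpf == 4)) {
    meas$value[i] <- pred$predicted[pred$observable_id ==
                                      meas$observable_id[i] &
                                      pred$condition_id ==
                                      meas$condition_id[i]]
  }
  problem <- make_problem(meas, "feedback", sigma_mode = sigma_mode)
  list(problem = problem, theta = theta)
}

# Naive per-measurement Gaussian NLL summation, independent of the package's
# likelihood bookkeeping: loops over rows, one term each.
naive_nll <- function(problem, theta, sigma) {
  pred <- predict_observables(problem, theta)
  total <- 0
  for (i in seq_len(nrow(problem$measurements))) {
    row <- problem$measurements[i, ]
    yhat <- pred$predicted[pred$observable_id == row$observable_id &
                             pred$condition_id == row$condition_id &
                             pred$time_dpf == row$time_dpf]
    s <- sigma[[row$observable_id]]
    total <- total + 0.5 * log(2 * pi) + log(s) +
      (yhat - row$value)^2 / (2 * s^2)
  }
  total
}
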