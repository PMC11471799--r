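test_that("apparent rates follow the condition switch", {
  p <- extended_parameters(k00 = 2, k3 = 1, alpha_hai1a = 0.5,
                           alpha_cer = -1)
  on <- apparent_rates(p, 1)
  off <- apparent_rates(p, 0)
  expect_equal(on$k3_app, 0.5)
  expect_equal(off$k3_app, 1.0)
  expect_equal(on$k00_app, 0.0)
  expect_equal(off$k00_app, 2.0)
})

test_that("parameter validation names the offending field", {
  expect_error(core_parameters(k0 = -1), "'k0'")
  expect_error(core_parameters(k0 = 1, k2r = -0.1), "'k2r'")
  expect_error(extended_parameters(k00 = 1, alpha_hai1a = 0.2),
               "'alpha_hai1a'")
  expect_error(extended_parameters(k00 = 1, alpha_cer = 0.5), "'alpha_cer'")
  expect_error(apparent_rates(extended_parameters(k00 = 1), 2), "s_on")
})

test_that("core rhs matches the stoichiometry-times-rate-vector oracle", {
  p <- core_parameters(k0 = 2, k1r = 0.3, k2f = 1.2, k2r = 0.4, k3 = 0.8,
                       k3r = 0.2, k4 = 1.5)
  expect_equal(unname(core_rhs(c(0, 0, 0), p)), c(2, 0, 0))
  set.seed(42)
  N <- matrix(c(1, -1, 0, 0,
                0, 1, -1, 0,
                0, 0, 1, -1), nrow = 3, byrow = TRUE)
  for (i in 1:25) {
    p <- draw_core_params()
    x <- stats::runif(3, 0.1, 5)
    v <- c(p$k0 - p$k1r * x[1],
           p$k2f * x[1] - p$k2r * x[2],
           p$k3 * x[2] - p$k3r * x[3],
           p$k4 * x[3])
    expect_equal(unname(core_rhs(x, p)), as.numeric(N %*% v),
                 tolerance = 1e-12)
  }
})

test_that("extended rhs matches its stoichiometry oracle and switch logic", {
  p <- extended_parameters(k00 = 1.5, k01 = 2, k2f = 1, k2r = 0.5, k3 = 2,
                           k3r = 0.1, k4 = 1, alpha_hai1a = 0.6,
                           alpha_cer = -1)
  expect_equal(unname(extended_rhs(c(0, 0, 0, 0), p, s_on = 0)),
               c(1.5, 0, 0, 0))
  # alpha_cer = -1 with the switch on: no de novo synthesis at all
  expect_equal(unname(extended_rhs(c(0.7, 0, 0, 0), p, s_on = 1))[1],
               -p$k01 * 0.7)
  set.seed(7)
  N <- matrix(c(1, -1, 0, 0, 0,
                0, 1, -1, 0, 0,
                0, 0, 1, -1, 0,
                0, 0, 0, 1, -1), nrow = 4, byrow = TRUE)
  for (s_on in c(0, 1)) {
    for (i in 1:10) {
      x <- stats::runif(4, 0.1, 5)
      k3a <- p$k3 * (1 - s_on * p$alpha_hai1a)
      k00a <- p$k00 * (1 + s_on * p$alpha_cer)
      v <- c(k00a, p$k01 * x[1],
             p$k2f * x[2] - p$k2r * x[3],
             k3a * x[3] - p$k3r * x[4],
             p$k4 * x[4])
      expect_equal(unname(extended_rhs(x, p, s_on)), as.numeric(N %*% v),
                   tolerance = 1e-12)
    }
  }
})

test_that("steady state has closed forms on irreversible chains", {
  p <- core_parameters(k0 = 3, k1r = 0, k2f = 1.5, k2r = 0, k3 = 0.6,
                       k3r = 0, k4 = 2)
  expect_equal(unname(steady_state("core", p)),
               c(3 / 1.5, 3 / 0.6, 3 / 2), tolerance = 1e-12)
  # irreversible unit chain relaxes to (1, 1, 1)
  tr <- simulate_model("core", irreversible_chain(), c(0, 0, 0),
                       times = c(0, 50))
  expect_equal(unname(tr$states[2, ]), c(1, 1, 1), tolerance = 1e-6)
  # extended model: terminal balance fixes S1P at k00_app / k4
  pe <- extended_parameters(k00 = 2, k01 = 1, k2f = 1, k2r = 0.3, k3 = 1.2,
                            k3r = 0.2, k4 = 0.8, alpha_hai1a = 0.5,
                            alpha_cer = -0.5)
  for (s_on in c(0, 1)) {
    app <- apparent_rates(pe, s_on)
    xs <- steady_state("extended", pe, s_on)
    expect_equal(xs[["s1p"]], app$k00_app / pe$k4, tolerance = 1e-12)
  }
})

test_that("rhs vanishes at the steady state and net fluxes chain", {
  set.seed(11)
  for (i in 1:25) {
    p <- draw_core_params()
    xs <- steady_state("core", p)
    expect_lt(max(abs(core_rhs(xs, p))), 1e-10)
    v <- c(p$k0 - p$k1r * xs[[1]],
           p$k2f * xs[[1]] - p$k2r * xs[[2]],
           p$k3 * xs[[2]] - p$k3r * xs[[3]],
           p$k4 * xs[[3]])
    expect_lt(max(abs(v[1:3] - v[4])), 1e-9 * (1 + abs(v[4])))
  }
})

test_that("steady state agrees with long-time integration", {
  set.seed(23)
  for (i in 1:10) {
    p <- draw_core_params()
    xs <- steady_state("core", p)
    tr <- simulate_model("core", p, c(0.5, 0.5, 0.5), times = c(0, 400))
    expect_equal(unname(tr$states[2, ]), unname(xs), tolerance = 1e-6)
  }
})

test_that("solver trajectories match the matrix-exponential closed form", {
  set.seed(31)
  times <- seq(0, 3, by = 0.5)
  for (i in 1:10) {
    p <- draw_core_params()
    A <- matrix(c(-(p$k1r + p$k2f), p$k2r, 0,
                  p$k2f, -(p$k2r + p$k3), p$k3r,
                  0, p$k3, -(p$k3r + p$k4)), nrow = 3, byrow = TRUE)
    b <- c(p$k0, 0, 0)
    x0 <- stats::runif(3, 0, 3)
    xs <- solve(A, -b)
    oracle <- t(vapply(times, function(t)
      as.numeric(xs + as.matrix(Matrix::expm(A * t)) %*% (x0 - xs)),
      numeric(3)))
    tr <- simulate_model("core", p, x0, times, method = "lsoda")
    expect_lt(max(abs(tr$states - oracle)), 1e-8)
    tra <- simulate_model("core", p, x0, times, method = "analytic")
    expect_lt(max(abs(tra$states - oracle)), 1e-10)
  }
})

test_that("a trajectory started at the steady state stays there", {
  p <- core_parameters(k0 = 1, k1r = 0.2, k2f = 1, k2r = 0.5, k3 = 2,
                       k3r = 0.1, k4 = 1)
  xs <- steady_state("core", p)
  tr <- simulate_model("core", p, xs, times = seq(0, 10, by = 1))
  expect_lt(max(abs(sweep(tr$states, 2, xs, "/") - 1)), 1e-6)
})

test_that("simulated states stay nonnegative from nonnegative starts", {
  set.seed(57)
  for (i in 1:20) {
    p <- draw_core_params()
    x0 <- stats::runif(3, 0, 5) * stats::rbinom(3, 1, 0.7)
    tr <- simulate_model("core", p, x0, times = seq(0, 5, by = 0.25))
    expect_gte(min(tr$states), 0)
  }
})

test_that("raising SphK lowers steady-state ceramide and sphingosine", {
  set.seed(91)
  for (i in 1:200) {
    p <- draw_core_params()
    xs <- steady_state("core", p)
    p_up <- unclass(p)
    p_up$k3 <- p_up$k3 * 1.01
    xs_up <- steady_state("core", do.call(core_parameters, p_up))
    expect_lt(xs_up[["ceramide"]], xs[["ceramide"]])
    expect_lt(xs_up[["sphingosine"]], xs[["sphingosine"]])
    # S1P is bounded by the total input flux over its degradation rate
    expect_lte(xs_up[["s1p"]], p$k0 / p$k4 * (1 + 1e-12))
  }
})

test_that("simulation input validation rejects bad states and times", {
  p <- irreversible_chain()
  expect_error(simulate_model("core", p, c(-1, 0, 0), c(0, 1)),
               "nonnegative")
  expect_error(simulate_model("core", p, c(0, 0, 0), c(1, 2)), "start at 0")
  expect_error(simulate_model("nope", p, c(0, 0, 0), c(0, 1)), "model_tag")
})
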