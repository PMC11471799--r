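# Affine-linear system assembly: dx/dt = A x + b. Both model variants are
# pure mass action with zero-order inputs, so A and b fully describe them.

core_system_matrices <- function(params) {
  with(params, {
    A <- matrix(c(
      -(k1r + k2f),  k2r,            0,
       k2f,          -(k2r + k3),    k3r,
       0,            k3,             -(k3r + k4)),
      nrow = 3, byrow = TRUE,
      dimnames = list(core_species, core_species))
    list(A = A, b = c(k0, 0, 0))
  })
}

extended_system_matrices <- function(params, s_on) {
  app <- apparent_rates(params, s_on)
  with(params, {
    A <- matrix(c(
      -k01,  0,     0,                    0,
       k01, -k2f,   k2r,                  0,
       0,    k2f,  -(k2r + app$k3_app),   k3r,
       0,    0,     app$k3_app,          -(k3r + k4)),
      nrow = 4, byrow = TRUE,
      dimnames = list(extended_species, extended_species))
    list(A = A, b = c(app$k00_app, 0, 0, 0))
  })
}

system_matrices <- function(model_tag, params, s_on = 0) {
  switch(model_tag,
         core = core_system_matrices(params),
         extended = extended_system_matrices(params, s_on),
         stop(sprintf("unknown model_tag '%s'", model_tag), call. = FALSE))
}

#' Right-hand side of the core rheostat ODE
#'
#' Time derivatives of (ceramide, sphingosine, S1P) under mass-action
#' kinetics:
#' \deqn{\dot x_1 = k_0 - k_{1r} x_1 - k_{2f} x_1 + k_{2r} x_2}
#' \deqn{\dot x_2 = k_{2f} x_1 - k_{2r} x_2 - k_3 x_2 + k_{3r} x_3}
#' \deqn{\dot x_3 = k_3 x_2 - k_{3r} x_3 - k_4 x_3}
#'
#' @param state numeric vector of length 3 (ceramide, sphingosine, S1P),
#'   nonnegative.
#' @param params a \code{\link{core_parameters}} object.
#' @return Named derivative vector (a.u. day^-1).
#' @export
core_rhs <- function(state, params) {
  stopifnot(inherits(params, "core_parameters"))
  state <- check_state(state, 3L, core_species)
  sys <- core_system_matrices(params)
  drop(sys$A %*% state) + sys$b
}

#' Right-hand side of the extended four-species ODE
#'
#' As \code{\link{core_rhs}} but with sphinganine upstream of ceramide and
#' condition-dependent apparent rates (\code{\link{apparent_rates}}):
#' \deqn{\dot x_{sa} = k_{00,app} - k_{01} x_{sa}}
#' \deqn{\dot x_{cer} = k_{01} x_{sa} - k_{2f} x_{cer} + k_{2r} x_{sph}}
#' \deqn{\dot x_{sph} = k_{2f} x_{cer} - k_{2r} x_{sph} - k_{3,app} x_{sph}
#'   + k_{3r} x_{s1p}}
#' \deqn{\dot x_{s1p} = k_{3,app} x_{sph} - k_{3r} x_{s1p} - k_4 x_{s1p}}
#'
#' @param state numeric vector of length 4 (sphinganine, ceramide,
#'   sphingosine, S1P), nonnegative.
#' @param params an \code{\link{extended_parameters}} object.
#' @param s_on condition switch (1 wild type, 0 mutant).
#' @return Named derivative vector (a.u. day^-1).
#' @export
extended_rhs <- function(state, params, s_on) {
  stopifnot(inherits(params, "extended_parameters"))
  state <- check_state(state, 4L, extended_species)
  sys <- extended_system_matrices(params, s_on)
  drop(sys$A %*% state) + sys$b
}

check_state <- function(state, n, species) {
  if (!is.numeric(state) || length(state) != n || any(!is.finite(state))) {
    stop(sprintf("state must be a finite numeric vector of length %d", n),
         call. = FALSE)
  }
  if (any(state < 0)) {
    stop("state components must be nonnegative", call. = FALSE)
  }
  stats::setNames(as.numeric(state), species)
}

#' Simulate a rheostat model
#'
#' Integrates the chosen model from a nonnegative initial state. Time zero
#' corresponds to 2 days post fertilization (dpf); rate constants are per
#' day. Two engines are available: \code{"lsoda"} (default) uses the
#' stiff-capable \pkg{deSolve} integrator, \code{"analytic"} evaluates the
#' exact solution of the affine-linear system,
#' \eqn{x(t) = x^* + e^{At}(x_0 - x^*)} with \eqn{x^* = -A^{-1} b}, via the
#' matrix exponential. The engines agree to solver tolerance and the
#' analytic one is used internally wherever speed matters.
#'
#' @param model_tag \code{"core"} or \code{"extended"}.
#' @param params matching parameter object.
#' @param x0 nonnegative initial state (at 2 dpf).
#' @param times numeric vector of output times (days since 2 dpf), strictly
#'   increasing, starting at 0.
#' @param s_on condition switch, used by the extended model only.
#' @param method \code{"lsoda"} or \code{"analytic"}.
#' @param rtol,atol solver tolerances (lsoda engine).
#' @return A \code{rheostat_trajectory}: list with \code{times},
#'   \code{states} (time x species matrix), \code{model_tag},
#'   \code{condition_id}.
#' @export
simulate_model <- function(model_tag, params, x0, times, s_on = 0,
                           method = c("lsoda", "analytic"),
                           rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  sys <- system_matrices(model_tag, params, s_on)
  n <- nrow(sys$A)
  x0 <- check_state(x0, n, rownames(sys$A))
  if (!is.numeric(times) || length(times) < 1L || times[1] != 0 ||
      is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing and start at 0 (= 2 dpf)",
         call. = FALSE)
  }
  states <- if (method == "analytic") {
    propagate_affine(sys$A, sys$b, x0, times)
  } else {
    rhs_fun <- function(t, y, p) list(drop(sys$A %*% y) + sys$b)
    sol <- deSolve::ode(y = x0, times = times, func = rhs_fun, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop("ODE integration failed; see deSolve diagnostics", call. = FALSE)
    }
    unname(as.matrix(sol)[, -1L, drop = FALSE])
  }
  # mass-action compartmental dynamics cannot leave the positive orthant;
  # clip the solver's tolerance-level undershoots only
  states[states < 0 & states > -1e-8] <- 0
  dimnames(states) <- list(NULL, rownames(sys$A))
  structure(list(times = times, states = states, model_tag = model_tag,
                 condition_id = if (model_tag == "extended")
                   condition_from_s_on(s_on) else NA_character_),
            class = "rheostat_trajectory")
}

condition_from_s_on <- function(s_on) {
  if (check_s_on(s_on) == 1) "wild_type" else "mutant"
}

# Exact solution of dx/dt = A x + b at the requested times.
propagate_affine <- function(A, b, x0, times) {
  xs <- solve(A, -b)
  dev0 <- x0 - xs
  t(vapply(times, function(t) {
    if (t == 0) return(as.numeric(x0))
    E <- as.matrix(Matrix::expm(A * t))
    as.numeric(xs + E %*% dev0)
  }, numeric(length(x0))))
}

#' Steady state of a rheostat model
#'
#' Solves the affine-linear balance equations \eqn{A x + b = 0} for the
#' unique steady state. With all forward chain rates and the terminal
#' degradation rate \code{k4} positive, the steady state exists, is unique
#' and nonnegative, and carries the effective downstream flux: every net
#' reaction rate equals the terminal degradation flux \eqn{v_4 = k_4 x_3^*}.
#'
#' @inheritParams simulate_model
#' @return Named nonnegative steady-state vector.
#' @export
steady_state <- function(model_tag, params, s_on = 0) {
  sys <- system_matrices(model_tag, params, s_on)
  xs <- tryCatch(solve(sys$A, -sys$b), error = function(e) {
    stop("no steady state: balance matrix is singular ",
         "(is k4 = 0 with no other outflow?)", call. = FALSE)
  })
  resid <- drop(sys$A %*% xs) + sys$b
  if (max(abs(resid)) > 1e-10 * (1 + max(abs(sys$b)))) {
    stop("steady-state solve did not satisfy the balance equations",
         call. = FALSE)
  }
  stats::setNames(pmax(as.numeric(xs), 0), rownames(sys$A))
}

# Net mass-action reaction rates of the core model at a state.
core_net_rates <- function(state, params) {
  with(params, c(
    v1 = k0 - k1r * state[[1]],
    v2 = k2f * state[[1]] - k2r * state[[2]],
    v3 = k3 * state[[2]] - k3r * state[[3]],
    v4 = k4 * state[[3]]))
}

# Stoichiometry of the core reactions v1..v4 over (ceramide, sphingosine,
# S1P); dx/dt = N v(x).
core_stoichiometry <- function() {
  matrix(c(
    1, -1,  0,  0,
    0,  1, -1,  0,
    0,  0,  1, -1),
    nrow = 3, byrow = TRUE,
    dimnames = list(core_species, core_reactions))
}

#' @export
print.rheostat_trajectory <- function(x, ...) {
  cat(sprintf("<rheostat_trajectory> %s model%s, %d time points over [%g, %g] days (0 = 2 dpf)\n",
              x$model_tag,
              if (!is.na(x$condition_id)) paste0(", ", x$condition_id) else "",
              length(x$times), min(x$times), max(x$times)))
  print(utils::head(cbind(time = x$times, x$states)))
  invisible(x)
}

#' @export
as.data.frame.rheostat_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states,
             model_tag = x$model_tag, condition_id = x$condition_id,
             check.names = FALSE)
}
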