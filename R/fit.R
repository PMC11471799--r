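# Multi-start maximum-likelihood fitting. The objective is the compiled
# profiled negative log-likelihood; positive parameters are optimised in
# log10 space, the modulation parameters alpha_* in native space, all under
# box bounds (bounded quasi-Newton, L-BFGS-B, finite-difference gradients).

# Flatten the measurement bookkeeping once per problem so each objective
# evaluation only assembles the parameter vector.
compile_problem_data <- function(problem) {
  obs <- problem$observables
  conds <- problem$conditions
  m <- problem$measurements
  obs_state <- match(obs$species, extended_species) - 1L
  latent <- setdiff(extended_species, obs$species)
  if (length(latent) != 1L) {
    stop("the compiled objective expects exactly one latent species",
         call. = FALSE)
  }
  m0 <- m[m$time_dpf == 2, ]
  mlater <- m[m$time_dpf > 2, ]
  t_later <- sort(unique(mlater$time_dpf)) - 2
  mean0 <- matrix(NA_real_, nrow(obs), nrow(conds))
  ss0 <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    for (c in seq_len(nrow(conds))) {
      v <- m0$value[m0$observable_id == obs$observable_id[i] &
                      m0$condition_id == conds$condition_id[c]]
      mean0[i, c] <- mean(v)
      ss0[i] <- ss0[i] + sum((v - mean(v))^2)
    }
  }
  list(obs_state = obs_state,
       latent_state = match(latent, extended_species) - 1L,
       latent = latent,
       s_on = as.numeric(conds$s_on),
       mean0 = mean0,
       ss0 = ss0,
       n_per_obs = as.numeric(table(factor(m$observable_id,
                                           levels = obs$observable_id))),
       t_later = t_later,
       m_cond = match(mlater$condition_id, conds$condition_id) - 1L,
       m_obs = match(mlater$observable_id, obs$observable_id) - 1L,
       m_time = match(mlater$time_dpf - 2, t_later) - 1L,
       m_val = mlater$value,
       scaling_ids = paste0("s_", obs$observable_id),
       x0_ids = rep(paste0("x0_", latent), nrow(conds)),
       sigma_ids = if (problem$sigma_mode == "estimate")
         paste0("sigma_", obs$observable_id) else character())
}

objective_from_data <- function(dat, problem, sigma_min, penalty) {
  function(theta) {
    nll_extended_cpp(
      rates = unname(theta[rate_ids]),
      alpha_hai1a = theta[["alpha_hai1a"]],
      alpha_cer = theta[["alpha_cer"]],
      scaling = unname(theta[dat$scaling_ids]),
      obs_state = dat$obs_state, latent_state = dat$latent_state,
      s_on = dat$s_on, mean0 = dat$mean0,
      x0_latent = unname(theta[dat$x0_ids]),
      t_later = dat$t_later, m_cond = dat$m_cond, m_obs = dat$m_obs,
      m_time = dat$m_time, m_val = dat$m_val, ss0 = dat$ss0,
      n_per_obs = dat$n_per_obs,
      sigma = unname(theta[dat$sigma_ids]),
      sigma_min = sigma_min, penalty = penalty)
  }
}

#' Optimiser settings
#'
#' @param maxit maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B convergence factor.
#' @param ndeps finite-difference step for the numerical gradient, on the
#'   transformed parameter scale. The objective is smooth, so a small step
#'   is safe; tighten it (e.g. \code{1e-6}) together with \code{factr} when
#'   high-precision optima are needed.
#' @param sigma_min lower clamp for noise parameters.
#' @param penalty objective value returned on model-evaluation failure
#'   (large-penalty policy; set \code{on_failure = "error"} in
#'   \code{\link{fit}} to raise instead).
#' @return List of settings.
#' @export
fit_control <- function(maxit = 200L, factr = 1e7, ndeps = 1e-3,
                        sigma_min = 1e-8, penalty = 1e10) {
  list(maxit = maxit, factr = factr, ndeps = ndeps, sigma_min = sigma_min,
       penalty = penalty)
}

#' Multi-start maximum-likelihood calibration
#'
#' Draws \code{n_starts} start vectors log-uniformly (uniformly for the
#' \code{alpha_*} parameters) within the parameter bounds and runs a
#' bounded quasi-Newton optimisation (L-BFGS-B) from each. The reported
#' estimate is the endpoint with the lowest profiled negative
#' log-likelihood. Reproducible given \code{seed}.
#'
#' @param problem a \code{\link{make_problem}} object.
#' @param n_starts number of random starts.
#' @param seed integer seed governing the start sampling.
#' @param extra_starts optional list of full named native parameter vectors
#'   appended as additional deterministic starts (e.g. warm starts from a
#'   nested variant).
#' @param control see \code{\link{fit_control}}.
#' @param on_failure \code{"penalty"} (default) or \code{"error"} for
#'   model-evaluation failures inside the objective.
#' @return A \code{fit_result}: list with \code{theta_hat} (full named
#'   native vector), \code{nll}, \code{sigma_hat}, \code{n_starts},
#'   \code{n_converged}, \code{seed}, \code{start_nlls}.
#' @export
fit <- function(problem, n_starts = 100L, seed = 1L, extra_starts = list(),
                control = fit_control(), on_failure = "penalty") {
  stopifnot(inherits(problem, "calibration_problem"), n_starts >= 0L,
            n_starts + length(extra_starts) >= 1L)
  tab <- problem$parameters
  free <- which(tab$estimate)
  if (!length(free)) stop("no free parameters to fit", call. = FALSE)
  dat <- compile_problem_data(problem)
  obj_full <- objective_from_data(dat, problem, control$sigma_min,
                                  control$penalty)
  theta0 <- full_theta(problem)
  scales <- tab$scale[free]
  lower_t <- to_transformed(tab$lower[free], scales)
  upper_t <- to_transformed(tab$upper[free], scales)
  obj_free <- function(par_t) {
    theta <- theta0
    theta[free] <- from_transformed(par_t, scales)
    val <- obj_full(theta)
    if (on_failure == "error" && val >= control$penalty) {
      stop("model evaluation failed during fitting", call. = FALSE)
    }
    val
  }
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * length(free), lower_t, upper_t),
                   nrow = n_starts, ncol = length(free), byrow = TRUE)
  for (es in extra_starts) {
    es <- check_theta(problem, es)
    starts <- rbind(starts,
                    to_transformed(es[tab$parameter_id[free]], scales))
  }
  results <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    results[[i]] <- tryCatch(
      stats::optim(starts[i, ], obj_free, method = "L-BFGS-B",
                   lower = lower_t, upper = upper_t,
                   control = list(maxit = control$maxit,
                                  factr = control$factr,
                                  ndeps = rep(control$ndeps,
                                              length(free)))),
      error = function(e) NULL)
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) {
    stop(sprintf("all %d starts failed during optimisation", nrow(starts)),
         call. = FALSE)
  }
  values <- vapply(results, function(r) if (is.null(r)) Inf else r$value,
                   numeric(1))
  best <- which.min(values)
  theta_hat <- theta0
  theta_hat[free] <- from_transformed(results[[best]]$par, scales)
  # residual-based sigma at the optimum (profiled or as cross-check)
  pred <- predict_observables(problem, theta_hat)
  mm <- merge(problem$measurements, pred,
              by = c("observable_id", "condition_id", "time_dpf"))
  sigma_hat <- vapply(problem$observables$observable_id, function(obs) {
    sel <- mm$observable_id == obs
    suppressWarnings(sigma_mle(mm$predicted[sel] - mm$value[sel]))
  }, numeric(1))
  structure(list(
    theta_hat = theta_hat, nll = values[best], sigma_hat = sigma_hat,
    variant = problem$variant, n_starts = nrow(starts),
    n_converged = sum(vapply(results, function(r)
      !is.null(r) && r$convergence == 0, logical(1))),
    seed = seed, start_nlls = ifelse(is.finite(values), values, NA_real_)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> variant = %s, NLL = %.6g (%d/%d starts converged, seed %d)\n",
              x$variant, x$nll, x$n_converged, x$n_starts, x$seed))
  cat("theta_hat:\n")
  print(signif(x$theta_hat, 4))
  invisible(x)
}

#' Feedback versus no-feedback model comparison
#'
#' Fits both model variants to the same measurements with shared settings
#' and judges them the way the modelling argument does: by whether the
#' 4-dpf sphinganine and ceramide predictions fall within the 95\%
#' confidence intervals of the data in both conditions. The feedback
#' variant nests the no-feedback one (\code{alpha_cer = 0} is feasible), so
#' its fit is additionally warm-started from the no-feedback optimum, which
#' guarantees the nesting inequality up to optimiser tolerance.
#'
#' @param measurements measurement data frame (see
#'   \code{\link{make_problem}}).
#' @param seed integer seed (start sampling for both fits derives from it).
#' @param n_starts random starts per variant.
#' @param sigma_mode,ci_method,control passed through.
#' @return A \code{model_comparison_report}: fits, per-variant
#'   \code{assess_fit} tables, \code{delta_nll}
#'   (no-feedback minus feedback), a verdict string, and provenance.
#' @export
compare_variants <- function(measurements, seed = 1L, n_starts = 25L,
                             sigma_mode = "profile", ci_method = "t",
                             control = fit_control()) {
  p_nf <- make_problem(measurements, "no_feedback", sigma_mode = sigma_mode)
  p_fb <- make_problem(measurements, "feedback", sigma_mode = sigma_mode)
  fit_nf <- fit(p_nf, n_starts = n_starts, seed = seed, control = control)
  fit_fb <- fit(p_fb, n_starts = n_starts, seed = seed + 1L,
                extra_starts = list(fit_nf$theta_hat), control = control)
  # basin sharing between the nested variants: polish the no-feedback fit
  # from the feedback optimum projected onto alpha_cer = 0, and re-warm the
  # feedback fit if that helps, so the comparison reflects the models, not
  # multi-start luck
  proj <- fit_fb$theta_hat
  proj[["alpha_cer"]] <- 0
  fit_nf2 <- fit(p_nf, n_starts = 0L, seed = seed,
                 extra_starts = list(fit_nf$theta_hat, proj),
                 control = control)
  if (fit_nf2$nll < fit_nf$nll) fit_nf <- fit_nf2
  if (fit_nf$nll < fit_fb$nll) {
    fit_fb <- fit(p_fb, n_starts = 0L, seed = seed + 1L,
                  extra_starts = list(fit_fb$theta_hat, fit_nf$theta_hat),
                  control = control)
  }
  ass_nf <- assess_fit(fit_nf, p_nf, ci_method = ci_method)
  ass_fb <- assess_fit(fit_fb, p_fb, ci_method = ci_method)
  key_inside <- function(ass) {
    sel <- ass$time_dpf > 2 &
      ass$observable_id %in% c("sphinganine", "ceramide")
    all(ass$inside[sel])
  }
  ok_nf <- key_inside(ass_nf)
  ok_fb <- key_inside(ass_fb)
  verdict <- if (ok_fb && !ok_nf) {
    "feedback variant places all 4-dpf sphinganine and ceramide predictions inside the 95% CIs; no-feedback variant does not"
  } else if (ok_fb && ok_nf) {
    "both variants place all 4-dpf sphinganine and ceramide predictions inside the 95% CIs"
  } else if (!ok_fb && ok_nf) {
    "only the no-feedback variant places all 4-dpf sphinganine and ceramide predictions inside the 95% CIs"
  } else {
    "neither variant places all 4-dpf sphinganine and ceramide predictions inside the 95% CIs"
  }
  structure(list(
    nll = c(no_feedback = fit_nf$nll, feedback = fit_fb$nll),
    delta_nll = fit_nf$nll - fit_fb$nll,
    theta_hat = list(no_feedback = fit_nf$theta_hat,
                     feedback = fit_fb$theta_hat),
    within_ci = list(no_feedback = ass_nf, feedback = ass_fb),
    key_cells_inside = c(no_feedback = ok_nf, feedback = ok_fb),
    verdict = verdict,
    provenance = list(package = "sphingorheostat",
                      version = as.character(utils::packageVersion("sphingorheostat")),
                      seed = as.integer(seed), n_starts = as.integer(n_starts),
                      sigma_mode = sigma_mode, ci_method = ci_method)),
    class = "model_comparison_report")
}

#' @export
print.model_comparison_report <- function(x, ...) {
  cat("<model_comparison_report>\n")
  cat(sprintf("  NLL: no_feedback = %.4f, feedback = %.4f (delta = %.4f)\n",
              x$nll[["no_feedback"]], x$nll[["feedback"]], x$delta_nll))
  cat(sprintf("  4-dpf key cells inside CI: no_feedback = %s, feedback = %s\n",
              x$key_cells_inside[["no_feedback"]],
              x$key_cells_inside[["feedback"]]))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}
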