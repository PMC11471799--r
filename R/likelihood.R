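#' Initial states from the 2-dpf measurements
#'
#' Implements the initial-condition convention: with observations at only
#' two time points, the 2-dpf measurements anchor the simulation. For every
#' observed species the initial model state is the 2-dpf sample mean in its
#' condition divided by the current scaling factor, so the predicted
#' observable at 2 dpf equals the sample mean exactly. Latent species (S1P
#' by default) take their initial value from the free parameter vector
#' (\code{x0_s1p}, shared across conditions: the conditions table carries
#' only the genotype switch).
#'
#' @param problem a \code{\link{make_problem}} object.
#' @param theta full named native parameter vector (see
#'   \code{\link{full_theta}}).
#' @return Named list over conditions of named initial state vectors.
#' @export
set_initial_from_data <- function(problem, theta = full_theta(problem)) {
  theta <- check_theta(problem, theta)
  m2 <- problem$measurements[problem$measurements$time_dpf == 2, ]
  lapply(stats::setNames(problem$conditions$condition_id,
                         problem$conditions$condition_id), function(cond) {
    x0 <- stats::setNames(numeric(4), extended_species)
    for (i in seq_len(nrow(problem$observables))) {
      obs <- problem$observables$observable_id[i]
      sp <- problem$observables$species[i]
      vals <- m2$value[m2$condition_id == cond & m2$observable_id == obs]
      if (!length(vals)) {
        stop(sprintf("no 2-dpf data for observable '%s', condition '%s'",
                     obs, cond), call. = FALSE)
      }
      x0[[sp]] <- mean(vals) / theta[[paste0("s_", obs)]]
    }
    latent <- setdiff(extended_species, problem$observables$species)
    for (sp in latent) {
      id <- paste0("x0_", sp)
      if (!id %in% names(theta)) {
        stop(sprintf("no free initial value '%s' for latent species", id),
             call. = FALSE)
      }
      x0[[sp]] <- theta[[id]]
    }
    x0
  })
}

#' Model predictions on the measurement scale
#'
#' Simulates each condition from the 2-dpf-anchored initial state and maps
#' the states to observables via the scaling factors.
#'
#' @inheritParams set_initial_from_data
#' @param times_dpf time points (dpf) to predict; defaults to those present
#'   in the measurements.
#' @return Data frame with \code{observable_id}, \code{condition_id},
#'   \code{time_dpf}, \code{predicted}.
#' @export
predict_observables <- function(problem, theta = full_theta(problem),
                                times_dpf = sort(unique(
                                  problem$measurements$time_dpf))) {
  theta <- check_theta(problem, theta)
  params <- theta_to_model_params(theta)
  x0s <- set_initial_from_data(problem, theta)
  sim_times <- sort(unique(c(0, times_dpf - 2)))
  keep <- match(times_dpf - 2, sim_times)
  out <- list()
  for (ci in seq_len(nrow(problem$conditions))) {
    cond <- problem$conditions$condition_id[ci]
    traj <- simulate_model("extended", params, x0s[[cond]],
                           times = sim_times,
                           s_on = problem$conditions$s_on[ci],
                           method = "analytic")
    for (oi in seq_len(nrow(problem$observables))) {
      obs <- problem$observables$observable_id[oi]
      sp <- problem$observables$species[oi]
      out[[length(out) + 1L]] <- data.frame(
        observable_id = obs, condition_id = cond, time_dpf = times_dpf,
        predicted = theta[[paste0("s_", obs)]] * traj$states[keep, sp])
    }
  }
  do.call(rbind, out)
}

#' Negative log-likelihood of a calibration problem
#'
#' For independent additive Gaussian noise with one noise parameter
#' \eqn{\sigma_i} per species, the negative log-likelihood is
#' \deqn{-\log L = \sum \left[ \tfrac12 \log(2\pi) + \log \sigma_i
#'   + \frac{(s_i x_i(t_k) - m_{jk})^2}{2 \sigma_i^2} \right]}
#' summed over all measurements, with \eqn{s_i} the species' scaling factor
#' and \eqn{x(t)} the simulated state under the 2-dpf initial-condition
#' convention. With \code{sigma_mode = "profile"} the \eqn{\sigma_i} are
#' replaced by their analytic conditional maximisers
#' (\code{\link{sigma_mle}}, clamped below at \code{sigma_min}), which is
#' exact for this likelihood; with \code{"estimate"} they are read from
#' \code{theta}.
#'
#' @inheritParams set_initial_from_data
#' @param engine \code{"cpp"} (compiled, used by the optimiser) or
#'   \code{"r"} (reference implementation). Both return identical values to
#'   numerical precision.
#' @param sigma_min lower clamp for profiled/estimated sigma.
#' @return Scalar negative log-likelihood (profiled where applicable).
#' @export
negative_log_likelihood <- function(problem, theta = full_theta(problem),
                                    engine = c("cpp", "r"),
                                    sigma_min = 1e-8) {
  engine <- match.arg(engine)
  theta <- check_theta(problem, theta)
  if (engine == "cpp") {
    dat <- compile_problem_data(problem)
    obj <- objective_from_data(dat, problem, sigma_min, penalty = NA_real_)
    val <- obj(theta)
    if (is.na(val)) stop("likelihood evaluation failed (model unsolvable)",
                         call. = FALSE)
    return(val)
  }
  pred <- predict_observables(problem, theta)
  m <- merge(problem$measurements, pred,
             by = c("observable_id", "condition_id", "time_dpf"))
  nll <- 0
  for (obs in problem$observables$observable_id) {
    r <- m$predicted[m$observable_id == obs] -
      m$value[m$observable_id == obs]
    sig <- if (problem$sigma_mode == "estimate") {
      theta[[paste0("sigma_", obs)]]
    } else {
      sigma_mle(r)
    }
    sig <- max(sig, sigma_min)
    nll <- nll + sum(0.5 * log(2 * pi) + log(sig) + r^2 / (2 * sig^2))
  }
  nll
}

#' Analytic maximum-likelihood noise estimate
#'
#' For Gaussian noise with known mean structure the conditional maximiser
#' of the likelihood in \eqn{\sigma} is the root-mean-square residual,
#' \eqn{\hat\sigma = \sqrt{\mathrm{mean}(r^2)}}. Used to profile the noise
#' parameters out of the optimisation and to cross-check jointly estimated
#' ones.
#'
#' @param residuals numeric vector of residuals for one species, or a named
#'   list of such vectors (one element per species).
#' @return Scalar (or named vector) \eqn{\hat\sigma}; exact zeros indicate
#'   a degenerate (noise-free) fit and are flagged with a warning.
#' @export
sigma_mle <- function(residuals) {
  if (is.list(residuals)) {
    return(vapply(residuals, sigma_mle, numeric(1)))
  }
  if (!length(residuals)) stop("empty residual set", call. = FALSE)
  s <- sqrt(mean(residuals^2))
  if (s == 0) {
    warning("all residuals zero: degenerate sigma estimate ",
            "(lower-bounded by sigma_min in optimisation)", call. = FALSE)
  }
  s
}

#' 95\% confidence intervals of the measurement cells
#'
#' Per (observable, condition, time) cell. The default is the Student-t
#' interval, \eqn{\bar m \pm t_{0.975, n-1} \, \mathrm{sd}/\sqrt{n}};
#' a bootstrap-percentile interval over replicate means is available since
#' plotting libraries commonly bootstrap their error bars.
#'
#' @param measurements measurement data frame (see
#'   \code{\link{make_problem}}).
#' @param method \code{"t"} or \code{"bootstrap"}.
#' @param level confidence level.
#' @param n_boot bootstrap resamples (bootstrap method).
#' @param seed seed for the bootstrap resampling.
#' @return Data frame with \code{observable_id}, \code{condition_id},
#'   \code{time_dpf}, \code{n}, \code{mean}, \code{ci_low}, \code{ci_high},
#'   \code{method}.
#' @export
ci95 <- function(measurements, method = c("t", "bootstrap"), level = 0.95,
                 n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  measurements <- validate_measurements(measurements)
  cells <- unique(measurements[c("observable_id", "condition_id",
                                 "time_dpf")])
  cells <- cells[order(cells$observable_id, cells$condition_id,
                       cells$time_dpf), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- measurements$observable_id == cells$observable_id[i] &
      measurements$condition_id == cells$condition_id[i] &
      measurements$time_dpf == cells$time_dpf[i]
    v <- measurements$value[sel]
    n <- length(v)
    if (n < 2) {
      stop(sprintf("cell (%s, %s, %g dpf) has %d replicate(s); >= 2 required for a CI",
                   cells$observable_id[i], cells$condition_id[i],
                   cells$time_dpf[i], n), call. = FALSE)
    }
    if (method == "t") {
      hw <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(v) / sqrt(n)
      lo <- mean(v) - hw
      hi <- mean(v) + hw
    } else {
      set.seed(seed + i)
      boots <- vapply(seq_len(n_boot),
                      function(b) mean(sample(v, n, replace = TRUE)),
                      numeric(1))
      qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                            names = FALSE)
      lo <- qs[1]
      hi <- qs[2]
    }
    data.frame(observable_id = cells$observable_id[i],
               condition_id = cells$condition_id[i],
               time_dpf = cells$time_dpf[i], n = n, mean = mean(v),
               ci_low = lo, ci_high = hi, method = method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confidence-interval coverage of a fitted model
#'
#' For every measurement cell, checks whether the fitted model's prediction
#' lies inside the cell's 95\% confidence interval — the coverage
#' criterion by which the feedback and no-feedback variants are judged.
#' Cells at 2 dpf are met by construction (initial-condition convention) and
#' are flagged as such.
#'
#' @param fit a \code{\link{fit}} result.
#' @param problem the fitted problem.
#' @param ci_method passed to \code{\link{ci95}}.
#' @return Data frame with prediction, interval bounds, \code{inside} and
#'   \code{at_initial_condition} per cell.
#' @export
assess_fit <- function(fit, problem, ci_method = "t") {
  stopifnot(inherits(fit, "fit_result"))
  ci <- ci95(problem$measurements, method = ci_method)
  pred <- predict_observables(problem, fit$theta_hat)
  out <- merge(ci, pred,
               by = c("observable_id", "condition_id", "time_dpf"))
  out$at_initial_condition <- out$time_dpf == 2
  out$inside <- out$ci_low <= out$predicted & out$predicted <= out$ci_high
  out$inside[out$at_initial_condition] <- TRUE
  out <- out[order(out$observable_id, out$condition_id, out$time_dpf), ]
  rownames(out) <- NULL
  out
}
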