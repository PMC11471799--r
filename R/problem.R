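# The calibration problem: model variant, conditions, observables,
# replicate-level measurements and a parameter table with bounds and
# transforms. Mirrors a strict subset of the PEtab problem layout
# (see R/petab.R for the on-disk form).

rate_ids <- c("k00", "k01", "k2f", "k2r", "k3", "k3r", "k4")

#' Assemble a calibration problem
#'
#' Builds the container consumed by \code{\link{negative_log_likelihood}},
#' \code{\link{fit}} and \code{\link{compare_variants}}. The model is the
#' extended four-species rheostat; the variant decides whether the feedback
#' parameter \code{alpha_cer} is estimated within [-1, 0]
#' (\code{"feedback"}) or fixed at 0 (\code{"no_feedback"}).
#'
#' @param measurements data frame with columns \code{observable_id},
#'   \code{condition_id}, \code{time_dpf}, \code{replicate}, \code{value}
#'   (pmol per mg protein, >= 0). Every condition needs measurements at
#'   2 dpf for each observable (the initial-condition convention).
#' @param variant \code{"no_feedback"} or \code{"feedback"}.
#' @param sigma_mode \code{"profile"} (noise parameters profiled out
#'   analytically, the default) or \code{"estimate"} (one free
#'   \code{sigma_*} per species in the optimisation).
#' @param observable_species named character vector mapping observable ids
#'   to model species.
#' @param conditions data frame with columns \code{condition_id},
#'   \code{s_on}.
#' @param rate_bounds length-2 numeric, bounds for all rate constants
#'   (day^-1, log-uniform sampling in between).
#' @param parameters optional replacement parameter table (advanced; used by
#'   the PEtab reader). Must contain exactly the canonical parameter ids.
#' @return A \code{calibration_problem} object.
#' @export
make_problem <- function(measurements,
                         variant = c("no_feedback", "feedback"),
                         sigma_mode = c("profile", "estimate"),
                         observable_species = c(sphinganine = "sphinganine",
                                                ceramide = "ceramide",
                                                sphingosine = "sphingosine"),
                         conditions = data.frame(
                           condition_id = c("wild_type", "mutant"),
                           s_on = c(1, 0)),
                         rate_bounds = c(1e-3, 1e3),
                         parameters = NULL) {
  variant <- match.arg(variant)
  sigma_mode <- match.arg(sigma_mode)
  measurements <- validate_measurements(measurements)
  problems <- character()
  bad_obs <- setdiff(unique(measurements$observable_id),
                     names(observable_species))
  if (length(bad_obs)) {
    problems <- c(problems, sprintf(
      "measurements reference undeclared observable(s): %s",
      paste(bad_obs, collapse = ", ")))
  }
  bad_cond <- setdiff(unique(measurements$condition_id),
                      conditions$condition_id)
  if (length(bad_cond)) {
    problems <- c(problems, sprintf(
      "measurements reference undeclared condition(s): %s",
      paste(bad_cond, collapse = ", ")))
  }
  bad_species <- setdiff(observable_species, extended_species)
  if (length(bad_species)) {
    problems <- c(problems, sprintf(
      "observables map to unknown species: %s",
      paste(bad_species, collapse = ", ")))
  }
  stop_invalid(problems, "calibration problem")
  # initial-condition convention requires 2-dpf data per observable/condition
  for (cond in conditions$condition_id) {
    for (obs in names(observable_species)) {
      hit <- measurements$condition_id == cond &
        measurements$observable_id == obs & measurements$time_dpf == 2
      if (!any(hit)) {
        stop(sprintf(
          "no 2-dpf measurements for observable '%s' in condition '%s'; the 2-dpf mean is required as initial condition",
          obs, cond), call. = FALSE)
      }
    }
  }
  par_tab <- default_parameter_table(variant, names(observable_species),
                                     conditions$condition_id, sigma_mode,
                                     rate_bounds)
  if (!is.null(parameters)) {
    if (!setequal(parameters$parameter_id, par_tab$parameter_id)) {
      stop("replacement parameter table does not cover the canonical parameter set",
           call. = FALSE)
    }
    par_tab <- parameters[match(par_tab$parameter_id,
                                parameters$parameter_id), , drop = FALSE]
    rownames(par_tab) <- NULL
  }
  structure(list(variant = variant, sigma_mode = sigma_mode,
                 conditions = conditions,
                 observables = data.frame(
                   observable_id = names(observable_species),
                   species = unname(observable_species)),
                 measurements = measurements, parameters = par_tab),
            class = "calibration_problem")
}

validate_measurements <- function(measurements) {
  required <- c("observable_id", "condition_id", "time_dpf", "replicate",
                "value")
  missing <- setdiff(required, names(measurements))
  if (length(missing)) {
    stop(sprintf("measurement table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  m <- as.data.frame(measurements)[required]
  problems <- character()
  if (!is.numeric(m$value) || any(!is.finite(m$value))) {
    problems <- c(problems, "'value' must be finite numeric")
  } else if (any(m$value < 0)) {
    problems <- c(problems, "'value' must be nonnegative")
  }
  if (!is.numeric(m$time_dpf) || any(!is.finite(m$time_dpf)) ||
      any(m$time_dpf < 2)) {
    problems <- c(problems, "'time_dpf' must be numeric and >= 2")
  }
  key <- interaction(m$observable_id, m$condition_id, m$time_dpf,
                     m$replicate, drop = TRUE)
  if (anyDuplicated(key)) {
    problems <- c(problems,
                  "(observable, condition, time, replicate) must be unique")
  }
  stop_invalid(problems, "measurement table")
  m
}

default_parameter_table <- function(variant, observable_ids, condition_ids,
                                    sigma_mode, rate_bounds) {
  row <- function(id, scale, lower, upper, nominal, estimate) {
    data.frame(parameter_id = id, scale = scale, lower = lower,
               upper = upper, nominal = nominal, estimate = estimate)
  }
  tab <- do.call(rbind, c(
    lapply(rate_ids, row, scale = "log10", lower = rate_bounds[1],
           upper = rate_bounds[2], nominal = 1, estimate = TRUE),
    list(row("alpha_hai1a", "lin", 0.5, 0.999, 0.5, TRUE),
         if (variant == "feedback")
           row("alpha_cer", "lin", -1, 0, -0.5, TRUE)
         else
           row("alpha_cer", "lin", -1, 0, 0, FALSE)),
    lapply(paste0("s_", observable_ids), row, scale = "log10",
           lower = 1e-3, upper = 1e3, nominal = 1, estimate = TRUE),
    # latent-species initial value at 2 dpf: one shared free parameter
    # (condition-specific overrides are not part of the dialect: the
    # conditions table carries only the genotype switch)
    list(row("x0_s1p", "log10", 1e-3, 1e3, 0.1, TRUE)),
    if (sigma_mode == "estimate")
      lapply(paste0("sigma_", observable_ids), row, scale = "log10",
             lower = 1e-8, upper = 1e3, nominal = 1, estimate = TRUE)))
  rownames(tab) <- NULL
  tab
}

#' Full native parameter vector of a problem
#'
#' Expands a (possibly partial, named) set of overrides into the full named
#' parameter vector on the native scale: every parameter starts at its
#' nominal value from the problem's parameter table, entries named in
#' \code{theta_free} are overridden. An unnamed \code{theta_free} must
#' match the free parameters in table order.
#'
#' @param problem a \code{\link{make_problem}} object.
#' @param theta_free named numeric overrides (or unnamed vector over the
#'   free parameters), native scale.
#' @return Named numeric vector over all parameters.
#' @export
full_theta <- function(problem, theta_free = NULL) {
  tab <- problem$parameters
  theta <- stats::setNames(tab$nominal, tab$parameter_id)
  if (!is.null(theta_free)) {
    free_ids <- tab$parameter_id[tab$estimate]
    if (is.null(names(theta_free))) {
      stopifnot(length(theta_free) == length(free_ids))
      names(theta_free) <- free_ids
    }
    unknown <- setdiff(names(theta_free), tab$parameter_id)
    if (length(unknown)) {
      stop(sprintf("unknown parameter(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    theta[names(theta_free)] <- theta_free
  }
  theta
}

check_theta <- function(problem, theta) {
  tab <- problem$parameters
  missing <- setdiff(tab$parameter_id, names(theta))
  if (length(missing)) {
    stop(sprintf("theta lacks parameter(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- !is.finite(theta[tab$parameter_id])
  if (any(bad)) {
    stop(sprintf("non-finite theta entries: %s",
                 paste(tab$parameter_id[bad], collapse = ", ")),
         call. = FALSE)
  }
  pos <- grepl("^(k|s_|x0_|sigma_)", tab$parameter_id)
  nonpos <- pos & theta[tab$parameter_id] <= 0
  if (any(nonpos)) {
    stop(sprintf("parameters must be positive: %s",
                 paste(tab$parameter_id[nonpos], collapse = ", ")),
         call. = FALSE)
  }
  theta[tab$parameter_id]
}

theta_to_model_params <- function(theta) {
  extended_parameters(k00 = theta[["k00"]], k01 = theta[["k01"]],
                      k2f = theta[["k2f"]], k2r = theta[["k2r"]],
                      k3 = theta[["k3"]], k3r = theta[["k3r"]],
                      k4 = theta[["k4"]],
                      alpha_hai1a = theta[["alpha_hai1a"]],
                      alpha_cer = theta[["alpha_cer"]])
}

to_transformed <- function(values, scales) {
  out <- values
  sel <- scales == "log10"
  out[sel] <- log10(values[sel])
  out
}

from_transformed <- function(values, scales) {
  out <- values
  sel <- scales == "log10"
  out[sel] <- 10^values[sel]
  out
}

#' @export
print.calibration_problem <- function(x, ...) {
  cat(sprintf("<calibration_problem> variant = %s, sigma handling = %s\n",
              x$variant, x$sigma_mode))
  cat(sprintf("  %d measurements, %d observables, %d conditions, %d free of %d parameters\n",
              nrow(x$measurements), nrow(x$observables), nrow(x$conditions),
              sum(x$parameters$estimate), nrow(x$parameters)))
  invisible(x)
}
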