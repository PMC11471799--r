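# Synthetic lipidomics-style data with the statistical structure the
# calibration assumes: two genotype conditions, measurements at 2 and 4 dpf,
# four biological replicates, additive Gaussian noise per species and a
# per-species scaling between model units and pmol per mg protein.

#' Study design of the synthetic measurements
#'
#' @param conditions named numeric vector mapping condition ids to their
#'   \code{s_on} switch (default wild type on, mutant off).
#' @param times_dpf measurement times in days post fertilization; 2 dpf is
#'   mandatory (initial-condition convention).
#' @param n_replicates biological replicates per cell, >= 2.
#' @param observables measured species.
#' @return A \code{synthetic_design} object.
#' @export
synthetic_design <- function(conditions = c(wild_type = 1, mutant = 0),
                             times_dpf = c(2, 4), n_replicates = 4L,
                             observables = c("sphinganine", "ceramide",
                                             "sphingosine")) {
  problems <- character()
  if (is.null(names(conditions)) || any(names(conditions) == "") ||
      !all(conditions %in% c(0, 1))) {
    problems <- c(problems, "'conditions' must be named values in {0, 1}")
  }
  if (!2 %in% times_dpf || any(times_dpf < 2)) {
    problems <- c(problems, "'times_dpf' must include 2 and contain no earlier times")
  }
  if (n_replicates < 2) {
    problems <- c(problems, "'n_replicates' must be >= 2")
  }
  if (!all(observables %in% extended_species)) {
    problems <- c(problems, "'observables' must be model species")
  }
  stop_invalid(problems, "synthetic_design")
  structure(list(conditions = conditions, times_dpf = sort(times_dpf),
                 n_replicates = as.integer(n_replicates),
                 observables = observables),
            class = "synthetic_design")
}

#' Ground-truth scenario emulating the lipidomics study design
#'
#' A documented preset of extended-model parameters, per-condition 2-dpf
#' initial states, per-species scaling factors and noise levels. The
#' feedback preset (\code{alpha_cer = -1}: de novo synthesis fully off in
#' wild type, on in the mutant) reproduces, in its noise-free trajectories,
#' the qualitative genotype pattern of the measured lipids: mutant ceramide
#' below wild type at 2 dpf but above it at 4 dpf, and mutant sphinganine
#' above wild type at 4 dpf. The no-feedback preset (\code{alpha_cer = 0})
#' shows no such crossing — elevated SphK alone depletes mutant ceramide.
#' Both patterns are asserted at construction.
#'
#' Magnitudes are set by the scaling factors to typical LC-MS scales:
#' ceramide in the hundreds of pmol per mg protein, sphingoid bases in the
#' units-to-tens range. Noise levels are those under which four replicates
#' give confidence intervals tight enough to discriminate the variants.
#'
#' @param variant \code{"feedback"} or \code{"no_feedback"}.
#' @return A \code{truth_scenario}: list with \code{variant}, \code{params}
#'   (\code{\link{extended_parameters}}), \code{x0} (per-condition model
#'   states at 2 dpf), \code{scaling}, \code{sigma} (per species, measured
#'   units).
#' @export
paper_like_truth <- function(variant = c("feedback", "no_feedback")) {
  variant <- match.arg(variant)
  params <- extended_parameters(
    k00 = 2.0, k01 = 0.6, k2f = 1.0, k2r = 0.5, k3 = 2.0, k3r = 0.1,
    k4 = 1.0, alpha_hai1a = 0.5,
    alpha_cer = if (variant == "feedback") -1 else 0)
  truth <- structure(list(
    variant = variant, params = params,
    x0 = list(wild_type = c(sphinganine = 0.4, ceramide = 1.0,
                            sphingosine = 0.4, s1p = 0.2),
              mutant = c(sphinganine = 0.3, ceramide = 0.7,
                         sphingosine = 0.3, s1p = 0.4)),
    scaling = c(sphinganine = 20, ceramide = 300, sphingosine = 25),
    sigma = c(sphinganine = 0.8, ceramide = 25, sphingosine = 1.2)),
    class = "truth_scenario")
  assert_truth_pattern(truth)
  truth
}

# Noise-free trajectories of a scenario over [0, t_end] days since 2 dpf.
truth_trajectories <- function(truth, times = c(0, 2)) {
  s_on <- c(wild_type = 1, mutant = 0)
  lapply(s_on, function(s) {
    cond <- if (s == 1) "wild_type" else "mutant"
    simulate_model("extended", truth$params, truth$x0[[cond]],
                   times = times, s_on = s, method = "analytic")
  })
}

assert_truth_pattern <- function(truth) {
  tr <- truth_trajectories(truth, times = seq(0, 2, by = 0.25))
  wt <- tr$wild_type$states
  mu <- tr$mutant$states
  last <- nrow(wt)
  if (any(wt < 0) || any(mu < 0)) {
    stop("truth scenario produces negative states", call. = FALSE)
  }
  if (!(mu[1, "ceramide"] < wt[1, "ceramide"])) {
    stop("truth scenario violates the 2-dpf pattern: mutant ceramide must start below wild type",
         call. = FALSE)
  }
  if (truth$variant == "feedback") {
    ok <- mu[last, "ceramide"] > wt[last, "ceramide"] &&
      mu[last, "sphinganine"] > wt[last, "sphinganine"]
    if (!ok) {
      stop("feedback truth scenario fails the 4-dpf crossing pattern (mutant ceramide and sphinganine above wild type)",
           call. = FALSE)
    }
  } else {
    if (!(mu[last, "ceramide"] < wt[last, "ceramide"])) {
      stop("no-feedback truth scenario must keep mutant ceramide below wild type at 4 dpf",
           call. = FALSE)
    }
  }
  invisible(truth)
}

#' Generate replicate-level synthetic measurements
#'
#' Simulates the scenario noise-free, maps states to measured units via the
#' scaling factors and adds independent Gaussian noise per replicate,
#' \eqn{m = s_i x_i(t) + \epsilon}, \eqn{\epsilon \sim N(0, \sigma_i^2)}.
#' Draws below zero are truncated to zero (abundances are nonnegative); the
#' number of truncation events is recorded in the \code{"n_truncated"}
#' attribute and is negligible at the preset noise levels. Byte-identical
#' tables result from identical (truth, design, seed).
#'
#' @param truth a \code{\link{paper_like_truth}} scenario.
#' @param design a \code{\link{synthetic_design}}.
#' @param seed integer seed.
#' @return Measurement data frame (columns \code{observable_id},
#'   \code{condition_id}, \code{time_dpf}, \code{replicate}, \code{value}).
#' @export
generate_measurements <- function(truth, design = synthetic_design(),
                                  seed = 1L) {
  stopifnot(inherits(truth, "truth_scenario"),
            inherits(design, "synthetic_design"))
  if (!all(design$observables %in% names(truth$scaling))) {
    stop("design observables missing from the truth scenario's scaling set",
         call. = FALSE)
  }
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      observable_id = design$observables,
                      time_dpf = design$times_dpf,
                      condition_id = names(design$conditions),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("observable_id", "condition_id", "time_dpf", "replicate")]
  tr <- list()
  for (cond in names(design$conditions)) {
    tr[[cond]] <- simulate_model("extended", truth$params, truth$x0[[cond]],
                                 times = design$times_dpf - 2,
                                 s_on = design$conditions[[cond]],
                                 method = "analytic")
  }
  noisefree <- mapply(function(obs, cond, t) {
    truth$scaling[[obs]] *
      tr[[cond]]$states[match(t - 2, tr[[cond]]$times), obs]
  }, grid$observable_id, grid$condition_id, grid$time_dpf)
  eps <- stats::rnorm(nrow(grid), 0,
                      truth$sigma[grid$observable_id])
  value <- noisefree + eps
  n_truncated <- sum(value < 0)
  if (n_truncated > 0) {
    message(sprintf("truncated %d negative draw(s) at 0", n_truncated))
  }
  grid$value <- pmax(value, 0)
  out <- grid[order(grid$condition_id, grid$time_dpf, grid$observable_id,
                    grid$replicate), ]
  rownames(out) <- NULL
  attr(out, "n_truncated") <- n_truncated
  out
}
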