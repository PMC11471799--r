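# Metabolic Control Analysis of the core rheostat. Control coefficients are
# normalized steady-state sensitivities to proportional scaling of whole
# reactions: a scaling p_j multiplies all rate constants of reaction j
# (k0 with k1r for v1; k2f with k2r for v2; k3 with k3r for v3; k4 for v4),
# the standard MCA convention under which the summation theorems hold.

#' Scaled elasticity matrix of the core model
#'
#' Elasticities are the local, normalized sensitivities of the net reaction
#' rates to the species concentrations at a reference state:
#' \eqn{\epsilon_{jk} = (\partial v_j / \partial x_k) (x_k / v_j)}. They are
#' the local ingredient from which control coefficients are built.
#'
#' @param params a \code{\link{core_parameters}} object.
#' @param state strictly positive reference state (defaults to the steady
#'   state).
#' @return 4 x 3 matrix (reaction x species).
#' @export
elasticities <- function(params, state = steady_state("core", params)) {
  stopifnot(inherits(params, "core_parameters"))
  state <- check_state(state, 3L, core_species)
  if (any(state <= 0)) {
    stop("scaled elasticities require a strictly positive state",
         call. = FALSE)
  }
  v <- core_net_rates(state, params)
  if (any(v == 0)) {
    stop(sprintf("zero net rate at reference state for %s: scaled elasticity undefined",
                 paste(names(v)[v == 0], collapse = ", ")), call. = FALSE)
  }
  dvdx <- with(params, matrix(c(
    -k1r, 0,    0,
     k2f, -k2r, 0,
     0,   k3,   -k3r,
     0,   0,    k4),
    nrow = 4, byrow = TRUE,
    dimnames = list(core_reactions, core_species)))
  sweep(sweep(dvdx, 2L, state, `*`), 1L, v, `/`)
}

#' Analytic control coefficients of the core rheostat
#'
#' Computes scaled flux and concentration control coefficients at the
#' steady state. With the affine-linear mass-action system
#' \eqn{\dot x = N \mathrm{diag}(p) v(x)} and reaction scalings \eqn{p_j},
#' implicit differentiation at \eqn{p = 1} gives
#' \eqn{\partial x^* / \partial p_j = -A^{-1} N_{\cdot j} v_j^*} with
#' \eqn{A = N \, \partial v/\partial x}; the concentration control
#' coefficients are \eqn{C^{x_i}_j = \partial \ln x_i^* / \partial \ln p_j}
#' and the flux control coefficients refer to the effective downstream flux
#' \eqn{J = v_4^*}. The summation theorems
#' (\eqn{\sum_j C^J_j = 1}, \eqn{\sum_j C^{x_i}_j = 0}) hold by construction
#' and are verified numerically on return.
#'
#' The biological reading: a negative ceramide coefficient with respect to
#' the SphK reaction v3 means that increasing S1P synthesis — the modelled
#' effect of the protease mutant — can only lower steady-state ceramide, so
#' the rheostat alone cannot produce ceramide over-production.
#'
#' @param params a \code{\link{core_parameters}} object.
#' @param scaled if \code{FALSE}, return unscaled sensitivities
#'   \eqn{\partial x^*/\partial p_j} and \eqn{\partial J/\partial p_j}
#'   instead of logarithmic coefficients.
#' @return A \code{control_coefficients} object: list with \code{c_flux}
#'   (length-4 vector over v1..v4), \code{c_conc} (3 x 4 species x reaction
#'   matrix), \code{reference_state}, \code{reference_params},
#'   \code{scaled}.
#' @export
control_coefficients <- function(params, scaled = TRUE) {
  stopifnot(inherits(params, "core_parameters"))
  xs <- steady_state("core", params)
  if (any(xs <= 0)) {
    stop("control coefficients require a strictly positive steady state",
         call. = FALSE)
  }
  v <- core_net_rates(xs, params)
  J <- v[["v4"]]
  if (J == 0) {
    stop("zero steady-state flux: control coefficients undefined",
         call. = FALSE)
  }
  N <- core_stoichiometry()
  A <- core_system_matrices(params)$A
  # dx*/dp_j = -A^{-1} N[,j] v_j*
  dxdp <- -solve(A, sweep(N, 2L, v, `*`))
  # J = p4 k4 x3*(p): dJ/dp_j = delta_{j4} J + k4 dx3*/dp_j
  dJdp <- params$k4 * dxdp["s1p", ] + c(0, 0, 0, J)
  if (scaled) {
    c_conc <- sweep(dxdp, 1L, xs, `/`)
    c_flux <- dJdp / J
  } else {
    c_conc <- dxdp
    c_flux <- dJdp
  }
  dimnames(c_conc) <- list(core_species, core_reactions)
  names(c_flux) <- core_reactions
  out <- structure(list(c_flux = c_flux, c_conc = c_conc,
                        reference_state = xs, reference_params = params,
                        scaled = scaled),
                   class = "control_coefficients")
  if (scaled) check_summation(out)
  out
}

check_summation <- function(cc, tol = 1e-6) {
  if (abs(sum(cc$c_flux) - 1) > tol ||
      max(abs(rowSums(cc$c_conc))) > tol) {
    stop("summation theorems violated beyond tolerance; ",
         "steady state may be ill-conditioned", call. = FALSE)
  }
  invisible(cc)
}

#' Finite-difference control coefficients
#'
#' Independent check of \code{\link{control_coefficients}}: each reaction's
#' rate constants are scaled by \eqn{1 \pm h} and the central difference of
#' the log steady state and log flux approximates the logarithmic
#' coefficients.
#'
#' @param params a \code{\link{core_parameters}} object.
#' @param rel_step relative perturbation \eqn{h}, in (0, 0.1].
#' @return A \code{control_coefficients} object (scaled coefficients).
#' @export
control_coefficients_fd <- function(params, rel_step = 1e-4) {
  stopifnot(inherits(params, "core_parameters"),
            is.numeric(rel_step), length(rel_step) == 1L,
            rel_step > 0, rel_step <= 0.1)
  xs <- steady_state("core", params)
  reaction_rates <- list(v1 = c("k0", "k1r"), v2 = c("k2f", "k2r"),
                         v3 = c("k3", "k3r"), v4 = "k4")
  eval_at <- function(reaction, factor) {
    p <- unclass(params)
    for (nm in reaction_rates[[reaction]]) p[[nm]] <- p[[nm]] * factor
    p <- do.call(core_parameters, p)
    x <- tryCatch(steady_state("core", p), error = function(e) {
      stop(sprintf("steady state failed while perturbing %s by factor %g: %s",
                   reaction, factor, conditionMessage(e)), call. = FALSE)
    })
    list(x = x, J = p$k4 * x[["s1p"]])
  }
  c_conc <- matrix(NA_real_, 3, 4,
                   dimnames = list(core_species, core_reactions))
  c_flux <- stats::setNames(numeric(4), core_reactions)
  denom <- log(1 + rel_step) - log(1 - rel_step)
  for (r in core_reactions) {
    up <- eval_at(r, 1 + rel_step)
    dn <- eval_at(r, 1 - rel_step)
    c_conc[, r] <- (log(up$x) - log(dn$x)) / denom
    c_flux[[r]] <- (log(up$J) - log(dn$J)) / denom
  }
  structure(list(c_flux = c_flux, c_conc = c_conc, reference_state = xs,
                 reference_params = params, scaled = TRUE),
            class = "control_coefficients")
}

#' @export
print.control_coefficients <- function(x, ...) {
  cat(sprintf("<control_coefficients> (%s)\n",
              if (x$scaled) "scaled, logarithmic" else "unscaled"))
  cat("flux control coefficients (J = v4):\n")
  print(round(x$c_flux, 6))
  cat("concentration control coefficients (species x reaction):\n")
  print(round(x$c_conc, 6))
  cer_v3 <- x$c_conc["ceramide", "v3"]
  cat(sprintf("ceramide response to SphK (v3): %.6g -> %s\n", cer_v3,
              if (cer_v3 <= 0)
                "elevated SphK cannot raise steady-state ceramide"
              else "unexpected positive ceramide response"))
  invisible(x)
}

#' Mutant-versus-wild-type steady-state perturbation report
#'
#' Emulates the protease mutant as a fold increase of the SphK rate
#' \code{k3} (the sole modelled entry point of the mutation) and reports the
#' ratio of mutant to wild-type steady states per species. A ceramide ratio
#' below one restates the MCA conclusion: the rheostat network alone
#' predicts ceramide depletion, not over-production, in the mutant.
#'
#' @param params wild-type \code{\link{core_parameters}}.
#' @param fold_change factor (> 1) applied to \code{k3} in the mutant.
#' @return A data frame with columns \code{species}, \code{wild_type},
#'   \code{mutant}, \code{ratio}, plus attribute
#'   \code{ceramide_depleted} (logical).
#' @export
k3_perturbation_report <- function(params, fold_change) {
  stopifnot(inherits(params, "core_parameters"),
            is.numeric(fold_change), length(fold_change) == 1L,
            fold_change >= 1)
  wt <- steady_state("core", params)
  p_mut <- unclass(params)
  p_mut$k3 <- p_mut$k3 * fold_change
  mut <- steady_state("core", do.call(core_parameters, p_mut))
  out <- data.frame(species = core_species, wild_type = as.numeric(wt),
                    mutant = as.numeric(mut),
                    ratio = as.numeric(mut / wt))
  attr(out, "fold_change") <- fold_change
  attr(out, "ceramide_depleted") <- out$ratio[out$species == "ceramide"] < 1
  out
}
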