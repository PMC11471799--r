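#' @useDynLib sphingorheostat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Shared validation helper: collect all violations, then fail once with a
# message naming every offending field.
stop_invalid <- function(problems, what) {
  if (length(problems)) {
    stop(sprintf("invalid %s: %s", what, paste(problems, collapse = "; ")),
         call. = FALSE)
  }
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE, problems) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    return(c(problems, sprintf("'%s' must be a finite numeric scalar", name)))
  }
  bad <- if (strict) x <= lower else x < lower
  if (bad) {
    cmp <- if (strict) ">" else ">="
    problems <- c(problems, sprintf("'%s' must be %s %g (got %g)",
                                    name, cmp, lower, x))
  }
  problems
}

#' Rate constants of the core three-species rheostat model
#'
#' The core scheme follows ceramide (x1), sphingosine (x2) and
#' sphingosine-1-phosphate (S1P, x3). Ceramide synthesis is a zero-order
#' boundary input \code{k0} with a first-order reverse exchange \code{k1r};
#' ceramide/sphingosine and sphingosine/S1P interconvert reversibly
#' (\code{k2f}/\code{k2r}, \code{k3}/\code{k3r}, where \code{k3} is the
#' sphingosine kinase step); S1P degradation \code{k4} is irreversible. All
#' rate laws are mass action, so the system is affine-linear in the state.
#'
#' @param k0 zero-order ceramide synthesis rate (a.u. day^-1), > 0.
#' @param k1r first-order reverse rate of the synthesis exchange (day^-1), >= 0.
#' @param k2f,k2r ceramide -> sphingosine forward/reverse rates (day^-1);
#'   \code{k2f} > 0, \code{k2r} >= 0.
#' @param k3,k3r sphingosine -> S1P forward (SphK) and reverse rates (day^-1);
#'   \code{k3} > 0, \code{k3r} >= 0.
#' @param k4 irreversible S1P degradation rate (day^-1), > 0.
#' @return An object of class \code{core_parameters}.
#' @export
core_parameters <- function(k0, k1r = 0, k2f = 1, k2r = 0, k3 = 1, k3r = 0,
                            k4 = 1) {
  p <- list(k0 = k0, k1r = k1r, k2f = k2f, k2r = k2r, k3 = k3, k3r = k3r,
            k4 = k4)
  problems <- character()
  for (nm in c("k0", "k2f", "k3", "k4")) {
    problems <- check_scalar(p[[nm]], nm, 0, strict = TRUE, problems)
  }
  for (nm in c("k1r", "k2r", "k3r")) {
    problems <- check_scalar(p[[nm]], nm, 0, strict = FALSE, problems)
  }
  stop_invalid(problems, "core_parameters")
  structure(p, class = "core_parameters")
}

#' Rate constants of the extended four-species model
#'
#' Extends the core rheostat upstream with sphinganine, the reporter of de
#' novo synthesis: a zero-order input \code{k00} feeds sphinganine, which is
#' converted to ceramide at rate \code{k01}; the downstream chain is as in
#' \code{\link{core_parameters}}. Two dimensionless modulation parameters make
#' rates condition dependent (see \code{\link{apparent_rates}}):
#' \code{alpha_hai1a} attenuates the SphK rate \code{k3} in wild type, where
#' the protease-inhibitor switch is on, and \code{alpha_cer} implements a
#' negative feedback on de novo synthesis, also acting in wild type.
#'
#' @param k00 zero-order sphinganine (de novo) synthesis rate
#'   (a.u. day^-1), > 0.
#' @param k01 sphinganine -> ceramide conversion rate (day^-1), > 0.
#' @param k2f,k2r,k3,k3r,k4 downstream rates as in
#'   \code{\link{core_parameters}}.
#' @param alpha_hai1a wild-type SphK attenuation, in [0.5, 1).
#' @param alpha_cer feedback attenuation of de novo synthesis, in [-1, 0];
#'   0 disables the feedback, -1 shuts synthesis off completely in wild type.
#' @return An object of class \code{extended_parameters}.
#' @export
extended_parameters <- function(k00, k01 = 1, k2f = 1, k2r = 0, k3 = 1,
                                k3r = 0, k4 = 1, alpha_hai1a = 0.5,
                                alpha_cer = 0) {
  p <- list(k00 = k00, k01 = k01, k2f = k2f, k2r = k2r, k3 = k3, k3r = k3r,
            k4 = k4, alpha_hai1a = alpha_hai1a, alpha_cer = alpha_cer)
  problems <- character()
  for (nm in c("k00", "k01", "k2f", "k3", "k4")) {
    problems <- check_scalar(p[[nm]], nm, 0, strict = TRUE, problems)
  }
  for (nm in c("k2r", "k3r")) {
    problems <- check_scalar(p[[nm]], nm, 0, strict = FALSE, problems)
  }
  if (!is.numeric(alpha_hai1a) || length(alpha_hai1a) != 1L ||
      !is.finite(alpha_hai1a) || alpha_hai1a < 0.5 || alpha_hai1a >= 1) {
    problems <- c(problems,
                  sprintf("'alpha_hai1a' must lie in [0.5, 1) (got %g)",
                          alpha_hai1a))
  }
  if (!is.numeric(alpha_cer) || length(alpha_cer) != 1L ||
      !is.finite(alpha_cer) || alpha_cer < -1 || alpha_cer > 0) {
    problems <- c(problems,
                  sprintf("'alpha_cer' must lie in [-1, 0] (got %g)",
                          alpha_cer))
  }
  stop_invalid(problems, "extended_parameters")
  structure(p, class = "extended_parameters")
}

#' Condition-dependent apparent rates
#'
#' The genotype enters the extended model through a Boolean switch
#' \code{s_on}, active (1) in wild type and inactive (0) in the
#' protease-inhibitor amorphic mutant. The apparent SphK rate is
#' \deqn{k_{3,app} = k_3 (1 - S_{on} \alpha_{hai1a}),}
#' at least 50\% lower in wild type than in the mutant, and the apparent de
#' novo synthesis rate is
#' \deqn{k_{00,app} = k_{00} (1 + S_{on} \alpha_{cer}),}
#' reduced (down to zero at \code{alpha_cer = -1}) in wild type when the
#' negative feedback is engaged. With \code{s_on = 0} both equal the raw
#' rates.
#'
#' @param params an \code{\link{extended_parameters}} object.
#' @param s_on condition switch, 1 (wild type) or 0 (mutant).
#' @return A list with elements \code{k3_app} and \code{k00_app} (day^-1 and
#'   a.u. day^-1).
#' @export
apparent_rates <- function(params, s_on) {
  stopifnot(inherits(params, "extended_parameters"))
  s_on <- check_s_on(s_on)
  list(k3_app = params$k3 * (1 - s_on * params$alpha_hai1a),
       k00_app = params$k00 * (1 + s_on * params$alpha_cer))
}

check_s_on <- function(s_on) {
  if (is.logical(s_on)) s_on <- as.numeric(s_on)
  if (!is.numeric(s_on) || length(s_on) != 1L || !s_on %in% c(0, 1)) {
    stop("'s_on' must be 0 (mutant) or 1 (wild type)", call. = FALSE)
  }
  s_on
}

core_species <- c("ceramide", "sphingosine", "s1p")
extended_species <- c("sphinganine", "ceramide", "sphingosine", "s1p")
core_reactions <- c("v1", "v2", "v3", "v4")
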