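#' Donnan equilibrium at an intermediate volume
#'
#' Solves the passive (Donnan) equilibrium of the permeant ions at a
#' prescribed extracellular volume fraction. Per-species particle totals are
#' fixed by the initial state; impermeant pools rescale with their
#' compartment's volume only. All permeant species share one Donnan ratio
#' `rho`: a species of valence `z` distributes as `Ki = Ko * rho^(-z)`, so
#' monovalent cations obey `Ko/Ki = rho` and monovalent anions `Ko/Ki =
#' 1/rho`, making every Nernst potential equal to the common Donnan potential
#' `(RT/F) ln rho` (inside-minus-outside).
#'
#' The solver brackets `log(rho)` in `[log(1e-8), log(1e8)]` and finds the
#' root of the outside electro-neutrality residual with Brent's method
#' ([stats::uniroot()], converged to about 1e-14 in `rho`); the residual is
#' strictly increasing in `rho`, so the root is unique. Inside
#' electro-neutrality follows from global charge conservation.
#'
#' @param model A [swell_model()] (supplies the initial state and constants).
#' @param alpha_tilde Extracellular volume fraction, in (0, 1).
#' @return Object of class `donnan_solution`: list with `alpha_tilde`, `rho`
#'   (Donnan ratio, outside/inside for cations), `potential` (Donnan
#'   potential, mV), `state` (a [tissue_state()]), and `residual` (the
#'   electro-neutrality residual at the root, mM).
#' @examples
#' m <- swell_model()
#' d <- donnan_equilibrium(m, 0.25)
#' d$state            # the concentrations of the alpha_tilde = 0.25 Donnan state
#' donnan_total_imbalance(d)  # about 171 mM excess solute inside
#' @export
donnan_equilibrium <- function(model, alpha_tilde) {
  stopifnot(inherits(model, "swell_model"))
  if (!is.numeric(alpha_tilde) || length(alpha_tilde) != 1 ||
      alpha_tilde <= 0 || alpha_tilde >= 1)
    stop("alpha_tilde must be a single number in (0, 1)")
  ions <- model$ions
  perm <- ions$permeant
  totals <- particle_totals(model$initial)
  z <- stats::setNames(ions$valence, ions$name)
  at <- alpha_tilde

  # impermeant pools rescale with their own compartment's volume
  imp_out <- model$alpha * model$initial$conc_out[!perm] / at
  imp_in <- (1 - model$alpha) * model$initial$conc_in[!perm] / (1 - at)
  imp_charge_out <- sum(z[!perm] * imp_out)

  out_conc <- function(rho)
    totals[perm] / (at + (1 - at) * rho^(-z[perm]))
  residual <- function(log_rho)
    sum(z[perm] * out_conc(exp(log_rho))) + imp_charge_out

  if (!any(perm)) stop("ion table has no permeant species")
  lo <- log(1e-8); hi <- log(1e8)
  f_lo <- residual(lo); f_hi <- residual(hi)
  if (is.nan(f_lo) || is.nan(f_hi) || f_lo * f_hi > 0)
    stop("Donnan ratio not bracketed in [1e-8, 1e8]")
  root <- stats::uniroot(residual, c(lo, hi), tol = 1e-15,
                         f.lower = f_lo, f.upper = f_hi)
  rho <- exp(root$root)

  Ko <- stats::setNames(rep(NA_real_, nrow(ions)), ions$name)
  Ki <- Ko
  Ko[perm] <- out_conc(rho)
  Ki[perm] <- Ko[perm] * rho^(-z[perm])
  Ko[!perm] <- imp_out
  Ki[!perm] <- imp_in
  state <- tissue_state(ions, at, Ko, Ki)
  potential <- 1000 * model$constants$RT / model$constants$faraday * log(rho)
  structure(list(alpha_tilde = at, rho = rho, potential = potential,
                 state = state, residual = residual(log(rho))),
            class = "donnan_solution")
}

#' @export
print.donnan_solution <- function(x, ...) {
  cat(sprintf("Donnan equilibrium at alpha_tilde = %.4f\n", x$alpha_tilde))
  cat(sprintf("  rho = %.6f, Donnan potential = %.2f mV\n", x$rho, x$potential))
  print(x$state)
  cat(sprintf("  Inside - outside total: %.1f mM\n", donnan_total_imbalance(x)))
  invisible(x)
}

#' Osmotic imbalance of a Donnan equilibrium
#'
#' Signed difference between the total intracellular and total extracellular
#' solute concentration. Positive values (solute excess inside) are the
#' osmotic stress that makes a Donnan state non-isotonic; the imbalance
#' vanishes exactly at the full-equilibrium volume `omega`, where the Donnan
#' state coincides with the endpoint of the isotonic path.
#'
#' @param sol A [donnan_equilibrium()] solution.
#' @return Inside-minus-outside total concentration, mM.
#' @export
donnan_total_imbalance <- function(sol) {
  stopifnot(inherits(sol, "donnan_solution"))
  total_concentration(sol$state, "inside") -
    total_concentration(sol$state, "outside")
}
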