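#' Tissue state at an intermediate volume on the isotonic path
#'
#' Evaluates the hyperbolic concentration-volume laws of the co-transport
#' path. For a permeant species with transport concentration `c_K`,
#' `Ko = c_K - (c_K - Ko_init)/w` and `Ki = c_K - (c_K - Ki_init)/y`, with
#' `w = alpha_tilde/alpha` and `y = (1 - alpha_tilde)/(1 - alpha)`.
#' Impermeant species follow pure volume rescaling (`Ko_init/w`, `Ki_init/y`).
#'
#' States below the full-equilibrium volume `omega` are admissible down to
#' `alpha_min` (the figures plot this super-equilibrium segment too); they
#' carry attribute `below_equilibrium = TRUE`.
#'
#' @param model A [swell_model()].
#' @param alpha_tilde Extracellular volume fraction, in `[alpha_min, alpha]`.
#' @return A [tissue_state()].
#' @examples
#' m <- swell_model()
#' path_state(m, 0.1)
#' @export
path_state <- function(model, alpha_tilde) {
  stopifnot(inherits(model, "swell_model"))
  if (!is.numeric(alpha_tilde) || length(alpha_tilde) != 1)
    stop("alpha_tilde must be a single number")
  if (alpha_tilde > model$alpha + 1e-12)
    stop("alpha_tilde exceeds the initial extracellular volume fraction alpha")
  if (alpha_tilde < model$alpha_min - 1e-12)
    stop(sprintf(paste0("alpha_tilde = %.4g is below the validity bound %.4g:",
                        " [%s] would become negative there"),
                 alpha_tilde, model$alpha_min, model$alpha_min_species))
  v <- volume_change(alpha_tilde, model$alpha)
  ions <- model$ions
  c_K <- model$plan$c_K
  Ko0 <- stats::setNames(ions$conc_out, ions$name)
  Ki0 <- stats::setNames(ions$conc_in, ions$name)
  Ko <- c_K - (c_K - Ko0) / v$w
  Ki <- c_K - (c_K - Ki0) / v$y
  imp <- !ions$permeant
  Ko[imp] <- Ko0[imp] / v$w
  Ki[imp] <- Ki0[imp] / v$y
  Ko <- pmax(Ko, 0); Ki <- pmax(Ki, 0)   # clip round-off at the depletion bound
  st <- tissue_state(ions, alpha_tilde, Ko, Ki)
  attr(st, "below_equilibrium") <- alpha_tilde < model$equilibrium$omega - 1e-12
  st
}

#' Validity range of the isotonic path
#'
#' The hyperbolic laws produce negative concentrations once the extracellular
#' volume fraction falls below the largest zero crossing over species; for the
#' physiological table this is where extracellular Na+ depletes, at
#' `alpha_tilde = alpha (c_Na - Na_out)/c_Na` (about 0.017, consistent with
#' the absence of physical solutions below about 0.02).
#'
#' @param model A [swell_model()].
#' @return List with `alpha_min` (smallest admissible extracellular volume
#'   fraction; 0 if no species ever depletes) and `species` (the binding
#'   species, `NA` if none).
#' @export
validity_range <- function(model) {
  stopifnot(inherits(model, "swell_model"))
  ions <- model$ions
  alpha <- model$alpha
  c_K <- model$plan$c_K
  Ko0 <- stats::setNames(ions$conc_out, ions$name)
  Ki0 <- stats::setNames(ions$conc_in, ions$name)
  bound <- stats::setNames(rep(0, nrow(ions)), ions$name)
  for (i in seq_len(nrow(ions))) {
    if (!ions$permeant[i] || !is.finite(c_K[i]) || c_K[i] == 0)
      next   # pure rescaling (or a degenerate w_e = 1 plan) never crosses 0
    # outer compartment: Ko(w) = c - (c - Ko0)/w hits 0 at w = (c - Ko0)/c
    if (c_K[i] > Ko0[i]) {
      w0 <- (c_K[i] - Ko0[i]) / c_K[i]
      bound[i] <- max(bound[i], alpha * w0)
    }
    # inner compartment: Ki(y) = c - (c - Ki0)/y hits 0 at y = (c - Ki0)/c,
    # reachable only if that y lies in (1, 1/(1 - alpha))
    y0 <- (c_K[i] - Ki0[i]) / c_K[i]
    if (is.finite(y0) && y0 > 1 && y0 < 1 / (1 - alpha))
      bound[i] <- max(bound[i], 1 - y0 * (1 - alpha))
  }
  i_max <- which.max(bound)
  list(alpha_min = bound[[i_max]],
       species = if (bound[[i_max]] > 0) names(bound)[i_max] else NA_character_)
}

#' Nernst equilibrium potential of an ion gradient
#'
#' `(RT/zF) ln(Ko/Ki)`, inside-minus-outside convention, in mV.
#'
#' @param Ko,Ki Outside and inside concentrations (mM, positive).
#' @param valence Signed ion charge.
#' @param constants A [swell_constants()].
#' @return Potential in mV (vectorised over species).
#' @examples
#' nernst_potential(148, 12, 1)  # about +67 mV for physiological Na+
#' @export
nernst_potential <- function(Ko, Ki, valence, constants = swell_constants()) {
  if (any(Ko <= 0) || any(Ki <= 0))
    stop("Nernst potential requires strictly positive concentrations")
  1000 * constants$RT / (valence * constants$faraday) * log(Ko / Ki)
}

#' Slope of one extracellular concentration against another on the path
#'
#' Along the isotonic path every extracellular concentration is linear in
#' `1/w`, so plotting one species against a reference species gives a straight
#' line whose slope is the ratio of the physiological concentration gradients,
#' `(Xo - Xi) / (Ro - Ri)`: -1 for Na+ against K+ and about -0.77 for Cl-
#' against K+ on the default table.
#'
#' @param model A [swell_model()].
#' @param species,reference Species names from the ion table.
#' @return Dimensionless slope `d[X]o / d[ref]o`.
#' @examples
#' interion_slope(swell_model(), "Cl", "K")
#' @export
interion_slope <- function(model, species, reference) {
  stopifnot(inherits(model, "swell_model"))
  ix <- match(species, model$ions$name)
  ir <- match(reference, model$ions$name)
  if (is.na(ix) || is.na(ir)) stop("unknown species name")
  dref <- model$ions$conc_out[ir] - model$ions$conc_in[ir]
  if (dref == 0) stop("reference species has zero physiological gradient")
  (model$ions$conc_out[ix] - model$ions$conc_in[ix]) / dref
}

#' Audit the isotonic path on a volume grid
#'
#' Evaluates [path_state()] on `n_points` volumes and reports the maximal
#' departures from isotonicity (both sides vs the initial total),
#' electro-neutrality, and per-species particle conservation. For a transport
#' plan that is itself isotonic and electro-neutral every residual is at
#' numerical round-off on the whole grid — all intermediate states inherit
#' those properties from the endpoints.
#'
#' @param model A [swell_model()].
#' @param n_points Grid size (at least 2).
#' @param from,to Grid limits; defaults to `[omega, alpha]`.
#' @return Object of class `path_audit`: list with `max_residuals` (named,
#'   mM), `grid` range, `n_points`, and logical `pass` at tolerance `tol`.
#' @param tol Pass/fail tolerance, mM (absolute).
#' @examples
#' audit_path(swell_model(), n_points = 100)
#' @export
audit_path <- function(model, n_points = 1000,
                       from = model$equilibrium$omega, to = model$alpha,
                       tol = 1e-9) {
  stopifnot(inherits(model, "swell_model"))
  if (n_points < 2) stop("n_points must be at least 2")
  grid <- seq(from, to, length.out = n_points)
  tot0 <- total_concentration(model$initial, "outside")
  n0 <- particle_totals(model$initial)
  res <- c(tonicity_out = 0, tonicity_in = 0, charge_out = 0, charge_in = 0,
           conservation = 0)
  per_point <- matrix(NA_real_, n_points, 5,
                      dimnames = list(NULL, names(res)))
  for (k in seq_along(grid)) {
    s <- path_state(model, grid[k])
    per_point[k, ] <- c(total_concentration(s, "outside") - tot0,
                        total_concentration(s, "inside") - tot0,
                        charge_imbalance(s, "outside"),
                        charge_imbalance(s, "inside"),
                        max(abs(particle_totals(s) - n0)))
  }
  res <- apply(abs(per_point), 2, max)
  structure(list(max_residuals = res, per_point = per_point, grid = grid,
                 n_points = n_points, tol = tol, pass = all(res < tol)),
            class = "path_audit")
}

#' @export
print.path_audit <- function(x, ...) {
  cat(sprintf("Isotonic path audit: %d points on [%.4f, %.4f] -- %s\n",
              x$n_points, min(x$grid), max(x$grid),
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  max residuals (mM, tol %.1g):\n", x$tol))
  print(signif(x$max_residuals, 3))
  invisible(x)
}
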