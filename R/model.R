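#' Fit the isotonic swelling model to a physiological ion table
#'
#' The central constructor of the package. Starting from an electro-neutral,
#' isotonic physiological state it solves, in closed form:
#'
#' * the state of full equilibrium — the extracellular volume fraction
#'   `omega = w_e * alpha` at which the impermeant anions reach the same
#'   concentration on both sides, where every permeant species can then
#'   equilibrate completely at its volume-weighted mean concentration
#'   `K_e = alpha * Ko + (1 - alpha) * Ki`;
#' * the transport plan — the constant concentration `c_K` at which each
#'   permeant species is co-transported with water along the path,
#'   `c_K = (Ko - w_e * K_e) / (1 - w_e)` (negative when ion and water move
#'   in opposite directions; identically 0 for impermeant species);
#' * the hyperbolic path coefficients `C = Vo * (1 - a_K * Ko)` and
#'   `D = Vi * (1 - a_K * Ki)` with `a_K = 1 / c_K`, and the minimal
#'   admissible extracellular volume fraction below which some concentration
#'   would turn negative.
#'
#' The resulting path keeps every intermediate state isotonic and
#' electro-neutral whenever the transport plan itself is isotonic
#' (`sum(c_K) =` initial total) and electro-neutral (`sum(z_K c_K) = 0`),
#' which the closed-form plan is by construction.
#'
#' @param ions An [ion_table()]; defaults to the packaged physiological table.
#' @param alpha Initial extracellular volume fraction (default 0.25).
#' @param constants A [swell_constants()] object.
#' @param c_override Optional named numeric vector overriding the transport
#'   concentration (mM) of selected permeant species, e.g.
#'   `c(Na = 179, K = -27)` for alternative isotonic plans. Overrides replace
#'   the closed-form values; the full-equilibrium state is unchanged.
#'
#' @return An object of class `swell_model` with components
#'   \describe{
#'     \item{ions, alpha, constants}{the inputs;}
#'     \item{initial}{the initial [tissue_state()];}
#'     \item{equilibrium}{list `w_e`, `omega`, `y`, `K_e` (named vector,
#'       impermeant entry included), the full-equilibrium [tissue_state()];}
#'     \item{plan}{list `c_K`, `a_K` (named vectors; `a_K` is `NA` where
#'       `c_K = 0`), logical `overridden`;}
#'     \item{path_constants}{per-species `C`, `D` (NA for impermeants) and
#'       the products `C_over_aK = Vo (c_K - Ko)`, `D_over_aK = Vi (c_K - Ki)`
#'       used by the energy formulas (finite for all species);}
#'     \item{alpha_min}{minimal admissible extracellular volume fraction on
#'       the path, and `alpha_min_species`, the species that depletes there.}
#'   }
#' @references The model solves the co-transport mixing rule
#'   `dV = a_K dK` for a closed two-compartment system.
#' @examples
#' m <- swell_model()
#' m$equilibrium$omega   # about 0.0243
#' coef(m)               # transport concentrations c_K
#' predict(m, alpha_tilde = 0.1)
#' @export
swell_model <- function(ions = physiological_ions(), alpha = 0.25,
                        constants = swell_constants(), c_override = NULL) {
  stopifnot(inherits(ions, "ion_table"), inherits(constants, "swell_constants"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  init <- tissue_state(ions, alpha, ions$conc_out, ions$conc_in)
  audit_state(init, tol = 1e-9, isotonic = TRUE)

  eq <- solve_full_equilibrium(init)

  c_K <- eq$c_K
  overridden <- FALSE
  if (!is.null(c_override)) {
    if (is.null(names(c_override)) || !all(names(c_override) %in% ions$name))
      stop("c_override must be named after species in the ion table")
    if (any(!ions$permeant[match(names(c_override), ions$name)]))
      stop("cannot override the transport concentration of an impermeant species")
    c_K[names(c_override)] <- c_override
    overridden <- TRUE
  }
  a_K <- ifelse(c_K == 0, NA_real_, 1 / c_K)
  names(a_K) <- names(c_K)

  Vo <- alpha; Vi <- 1 - alpha
  Ko <- stats::setNames(ions$conc_out, ions$name)
  Ki <- stats::setNames(ions$conc_in, ions$name)
  path_constants <- list(
    C = Vo * (1 - a_K * Ko), D = Vi * (1 - a_K * Ki),
    C_over_aK = Vo * (c_K - Ko), D_over_aK = Vi * (c_K - Ki))

  model <- structure(list(ions = ions, alpha = alpha, constants = constants,
                          initial = init, equilibrium = eq,
                          plan = list(c_K = c_K, a_K = a_K,
                                      overridden = overridden),
                          path_constants = path_constants),
                     class = "swell_model")
  vr <- validity_range(model)
  model$alpha_min <- vr$alpha_min
  model$alpha_min_species <- vr$species
  model
}

#' Solve the state of full equilibrium
#'
#' Finds the relative extracellular volume change `w_e` at which the
#' impermeant anions acquire the same concentration outside and inside
#' (`Ao/w = Ai (1 - alpha) / (1 - w alpha)`), solved in closed form as
#' `w_e = Ao / (Ai (1 - alpha) + alpha Ao)`. At this volume every permeant
#' species equilibrates completely to `K_e`, and the transport
#' concentrations `c_K` follow from the endpoint conditions.
#'
#' @param initial A [tissue_state()] (electro-neutral and isotonic).
#' @return List with `w_e`, `omega`, `y`, named vectors `K_e` and `c_K`, and
#'   `state`, the full-equilibrium [tissue_state()].
#' @examples
#' eq <- solve_full_equilibrium(initial_state())
#' eq$omega  # 0.0243
#' eq$K_e
#' @export
solve_full_equilibrium <- function(initial) {
  stopifnot(inherits(initial, "tissue_state"))
  ions <- initial$ions
  alpha <- initial$alpha_tilde
  imp <- !ions$permeant
  if (!any(imp)) stop("ion table has no impermeant species")
  Ao <- sum(initial$conc_out[imp]); Ai <- sum(initial$conc_in[imp])
  if (Ao <= 0 || Ai <= 0)
    stop("impermeant concentrations must be positive on both sides")
  w_e <- Ao / (Ai * (1 - alpha) + alpha * Ao)
  if (w_e <= 0 || w_e > 1)
    stop(sprintf(paste0("no shrinkage solution: impermeant-anion equalisation",
                        " requires w in (0, 1], got %.4g (needs inside",
                        " concentration above outside)"), w_e))
  omega <- w_e * alpha
  y <- (1 - omega) / (1 - alpha)

  Ko <- stats::setNames(initial$conc_out, ions$name)
  Ki <- stats::setNames(initial$conc_in, ions$name)
  K_e <- alpha * Ko + (1 - alpha) * Ki          # permeant equilibration
  K_e[imp] <- Ko[imp] / w_e                     # impermeants: volume rescaling
  c_K <- if (w_e < 1) (Ko - w_e * K_e) / (1 - w_e)
         else stats::setNames(rep(NaN, length(Ko)), names(Ko))
  c_K[imp] <- 0

  K_in_e <- K_e
  K_in_e[imp] <- Ki[imp] / y
  state <- tissue_state(ions, omega, K_e, K_in_e)
  list(w_e = w_e, omega = omega, y = y, K_e = K_e, c_K = c_K, state = state)
}

#' Transport concentration from endpoint conditions
#'
#' The constant co-transport concentration of a species can be computed from
#' either compartment's endpoint: `c_K = (Ko_init - w Ko_final) / (1 - w)`
#' (outer) or `c_K = (Ki_init - y Ki_final) / (1 - y)` (inner). Particle
#' conservation guarantees both give the same value.
#'
#' @param K_init,K_final Initial and final concentration in the compartment, mM.
#' @param rel_volume Relative volume change of that compartment (`w` or `y`).
#' @return Transport concentration `c_K`, mM.
#' @export
transport_concentration <- function(K_init, K_final, rel_volume) {
  if (any(rel_volume == 1)) stop("relative volume change of 1 leaves c_K undefined")
  (K_init - rel_volume * K_final) / (1 - rel_volume)
}

#' @export
print.swell_model <- function(x, ...) {
  eq <- x$equilibrium
  cat("Isotonic two-compartment swelling model\n")
  cat(sprintf("  %d ion species, alpha = %.4g, T = %g K\n",
              nrow(x$ions), x$alpha, x$constants$temperature))
  cat(sprintf("  Full equilibrium: w_e = %.4f, omega = %.4f, y = %.4f\n",
              eq$w_e, eq$omega, eq$y))
  cat(sprintf("  Path valid down to alpha_tilde = %.4f (%s depletes)\n",
              x$alpha_min,
              if (is.na(x$alpha_min_species)) "nothing" else x$alpha_min_species))
  if (x$plan$overridden) cat("  (transport plan contains user overrides)\n")
  cat("  Transport concentrations c_K (mM):\n")
  print(round(x$plan$c_K, 1))
  invisible(x)
}

#' @export
coef.swell_model <- function(object, ...) object$plan$c_K

#' Summarise a fitted swelling model
#'
#' @param object A [swell_model()].
#' @param ... Unused.
#' @return An object of class `summary.swell_model`: the species table with
#'   equilibrium concentrations and transport plan, path bounds, and the
#'   transport-plan invariants (total and net charge of the transported mix).
#' @export
summary.swell_model <- function(object, ...) {
  eq <- object$equilibrium
  perm <- object$ions$permeant
  tab <- data.frame(species = object$ions$name,
                    valence = object$ions$valence,
                    permeant = perm,
                    conc_out = object$ions$conc_out,
                    conc_in = object$ions$conc_in,
                    K_e = as.numeric(eq$K_e),
                    c_K = as.numeric(object$plan$c_K))
  structure(list(table = tab, alpha = object$alpha,
                 w_e = eq$w_e, omega = eq$omega, y = eq$y,
                 alpha_min = object$alpha_min,
                 alpha_min_species = object$alpha_min_species,
                 plan_total = sum(object$plan$c_K[perm]),
                 plan_charge = sum((object$ions$valence * object$plan$c_K)[perm]),
                 initial_total = total_concentration(object$initial, "outside")),
            class = "summary.swell_model")
}

#' @export
print.summary.swell_model <- function(x, ...) {
  cat("Isotonic swelling model summary\n\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("\nFull equilibrium: w_e = %.4f, omega = %.4f, y = %.4f\n",
              x$w_e, x$omega, x$y))
  cat(sprintf("Path validity:    alpha_tilde >= %.4f\n", x$alpha_min))
  cat(sprintf("Transport plan:   total %.4g mM (initial total %.4g), net charge %.3g mM\n",
              x$plan_total, x$initial_total, x$plan_charge))
  invisible(x)
}

#' Concentrations along the isotonic path
#'
#' Evaluates the hyperbolic concentration-volume laws at the requested
#' extracellular volume fractions (see [path_state()]).
#'
#' @param object A [swell_model()].
#' @param alpha_tilde Numeric vector of extracellular volume fractions,
#'   each in `[alpha_min, alpha]`.
#' @param ... Unused.
#' @return A long-format `data.frame` with columns `alpha_tilde`, `species`,
#'   `conc_out`, `conc_in` (mM).
#' @export
predict.swell_model <- function(object, alpha_tilde = object$equilibrium$omega,
                                ...) {
  out <- lapply(alpha_tilde, function(a) {
    s <- path_state(object, a)
    data.frame(alpha_tilde = a, species = object$ions$name,
               conc_out = as.numeric(s$conc_out),
               conc_in = as.numeric(s$conc_in))
  })
  do.call(rbind, out)
}

#' Conservation residuals along the isotonic path
#'
#' For a grid of intermediate volumes, returns how far each path state departs
#' from isotonicity, electro-neutrality and per-species particle conservation
#' (all should be at numerical round-off for a consistent transport plan; see
#' [audit_path()] for a pass/fail summary).
#'
#' @param object A [swell_model()].
#' @param n_points Number of grid points between `omega` and `alpha`.
#' @param ... Unused.
#' @return A `data.frame` with columns `alpha_tilde`, `tonicity_out`,
#'   `tonicity_in`, `charge_out`, `charge_in`, `conservation` (mM; the last is
#'   the maximum absolute per-species particle-total deviation).
#' @export
residuals.swell_model <- function(object, n_points = 101, ...) {
  grid <- seq(object$equilibrium$omega, object$alpha, length.out = n_points)
  tot0 <- total_concentration(object$initial, "outside")
  n0 <- particle_totals(object$initial)
  rows <- lapply(grid, function(a) {
    s <- path_state(object, a)
    data.frame(alpha_tilde = a,
               tonicity_out = total_concentration(s, "outside") - tot0,
               tonicity_in = total_concentration(s, "inside") - tot0,
               charge_out = charge_imbalance(s, "outside"),
               charge_in = charge_imbalance(s, "inside"),
               conservation = max(abs(particle_totals(s) - n0)))
  })
  do.call(rbind, rows)
}

#' Plot the fitted swelling model
#'
#' @param x A [swell_model()].
#' @param what `"concentrations"` (extra/intracellular concentration-volume
#'   curves), `"nernst"` (per-species Nernst potentials vs the Donnan
#'   potential), or `"energy"` (work of mixing and osmotic work totals).
#' @param n_points Grid resolution.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted grid data.
#' @export
plot.swell_model <- function(x, what = c("concentrations", "nernst", "energy"),
                             n_points = 101, ...) {
  what <- match.arg(what)
  grid <- seq(x$equilibrium$omega, x$alpha, length.out = n_points)
  if (what == "concentrations") {
    pr <- predict(x, grid)
    co <- stats::reshape(pr[c("alpha_tilde", "species", "conc_out")],
                         idvar = "alpha_tilde", timevar = "species",
                         direction = "wide")
    graphics::matplot(co$alpha_tilde, co[-1], type = "l", lty = 1,
                      xlab = "extracellular volume fraction",
                      ylab = "extracellular concentration (mM)", ...)
    graphics::legend("topright", legend = x$ions$name, lty = 1,
                     col = seq_len(nrow(x$ions)), bty = "n")
    return(invisible(co))
  }
  if (what == "nernst") {
    perm <- x$ions$permeant
    v <- sapply(grid, function(a) {
      s <- path_state(x, a)
      nernst_potential(s$conc_out[perm], s$conc_in[perm],
                       x$ions$valence[perm], x$constants)
    })
    graphics::matplot(grid, t(v), type = "l", lty = 1,
                      xlab = "extracellular volume fraction",
                      ylab = "Nernst potential (mV)", ...)
    graphics::legend("topright", legend = x$ions$name[perm], lty = 1,
                     col = seq_len(sum(perm)), bty = "n")
    return(invisible(t(v)))
  }
  e <- t(sapply(grid, function(a) {
    b <- isotonic_energy(x, a)
    c(mixing = b$total_mixing, osmotic = b$total_osmotic)
  }))
  graphics::matplot(grid, e, type = "l", lty = 1,
                    xlab = "extracellular volume fraction",
                    ylab = "work (J per litre tissue)", ...)
  graphics::legend("topright", legend = c("mixing", "osmotic"), lty = 1,
                   col = 1:2, bty = "n")
  invisible(e)
}
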