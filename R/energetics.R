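# Energy bookkeeping. All energies are densities in J per litre of tissue:
# concentrations in mM times volume fractions give mmol/l, so mM * (J/mol)
# quantities carry a factor 1e-3.

.xlogx <- function(k) ifelse(k > 0, k * log(k), 0)

# closed-form work of mixing per species (vectorised):
# RT * [ Vo Ko0 ln Ko0 - w Vo KoF ln KoF + Vi Ki0 ln Ki0 - y Vi KiF ln KiF
#        + Vo (c - Ko0) ln w + Vi (c - Ki0) ln y ] * 1e-3
# The last two terms are (C/a_K) ln w and (D/a_K) ln y written in the c->0
# safe form; with c = 0 the whole expression cancels to exactly 0 (pure
# volume rescaling does no mixing work).
.eq12 <- function(cst, alpha, Ko0, Ki0, KoF, KiF, w, y, c_K, permeant) {
  if (any(KoF < 0) || any(KiF < 0))
    stop("final concentrations must be non-negative")
  Vo <- alpha; Vi <- 1 - alpha
  val <- cst$RT * 1e-3 *
    (Vo * .xlogx(Ko0) - w * Vo * .xlogx(KoF) +
     Vi * .xlogx(Ki0) - y * Vi * .xlogx(KiF) +
     Vo * (c_K - Ko0) * log(w) + Vi * (c_K - Ki0) * log(y))
  val[!permeant | c_K == 0] <- 0
  val
}

# decrease in chemical potential energy (first four closed-form terms)
.chem_drop <- function(cst, alpha, Ko0, Ki0, KoF, KiF, w, y) {
  Vo <- alpha; Vi <- 1 - alpha
  cst$RT * 1e-3 *
    (Vo * .xlogx(Ko0) - w * Vo * .xlogx(KoF) +
     Vi * .xlogx(Ki0) - y * Vi * .xlogx(KiF))
}

# osmotic (pressure-volume) work per species, outer + inner compartment
.osmotic <- function(cst, alpha, Ko0, Ki0, w, y, c_K, split = FALSE) {
  if (any(w <= 0)) stop("w must be positive")
  Vo <- alpha; Vi <- 1 - alpha
  outer <- cst$RT * 1e-3 * (-alpha * (1 - w) * c_K - Vo * (c_K - Ko0) * log(w))
  inner <- cst$RT * 1e-3 * (alpha * (1 - w) * c_K - Vi * (c_K - Ki0) * log(y))
  if (split) cbind(outer = outer, inner = inner) else outer + inner
}

.species_args <- function(model) {
  list(Ko0 = stats::setNames(model$ions$conc_out, model$ions$name),
       Ki0 = stats::setNames(model$ions$conc_in, model$ions$name),
       perm = model$ions$permeant)
}

#' Work of mixing along the isotonic path (closed form)
#'
#' Gibbs energy retrieved by the reversible transfer of each species from the
#' physiological state down to extracellular volume fraction `alpha_tilde`,
#' evaluated with the closed-form solution of the mixing integral. Species
#' that only rescale with volume (the impermeant anions, or any species with
#' zero transport concentration) do no mixing work and return exactly 0.
#'
#' @param model A [swell_model()].
#' @param alpha_tilde Path endpoint; defaults to the full-equilibrium volume.
#' @param species Optional character vector to subset the result.
#' @return Named vector of energies, J per litre of tissue.
#' @examples
#' m <- swell_model()
#' mixing_work_closed(m)           # 138.5, 8.6, 109.4, 13.3 and 0 J/l
#' sum(mixing_work_closed(m))      # 269.8 J/l
#' @export
mixing_work_closed <- function(model, alpha_tilde = model$equilibrium$omega,
                               species = NULL) {
  stopifnot(inherits(model, "swell_model"))
  v <- volume_change(alpha_tilde, model$alpha)
  s <- path_state(model, alpha_tilde)
  a <- .species_args(model)
  out <- .eq12(model$constants, model$alpha, a$Ko0, a$Ki0,
               s$conc_out, s$conc_in, v$w, v$y, model$plan$c_K, a$perm)
  if (!is.null(species)) out <- out[species]
  out
}

#' Work of mixing by numerical quadrature (independent check)
#'
#' Integrates the mixing work `RT ln(Ko/Ki) d(Ko Vo)` along the parameterised
#' path with the composite trapezoid rule. On the path,
#' `d(Ko Vo) = alpha c_K dw`, so the integrand is
#' `RT alpha c_K ln(Ko(w)/Ki(w))` over `w` from `alpha_tilde/alpha` to 1. The
#' integrand is smooth and monotone, and the quadrature serves as an
#' independent oracle for the closed form.
#'
#' @inheritParams mixing_work_closed
#' @param species Single species name.
#' @param n_steps Number of trapezoid panels (at least 100; default 1e5).
#' @return Energy, J per litre of tissue.
#' @export
mixing_work_numeric <- function(model, species,
                                alpha_tilde = model$equilibrium$omega,
                                n_steps = 1e5) {
  stopifnot(inherits(model, "swell_model"))
  if (n_steps < 100) stop("n_steps must be at least 100")
  i <- match(species, model$ions$name)
  if (is.na(i)) stop("unknown species name")
  c_K <- model$plan$c_K[[i]]
  if (!model$ions$permeant[i] || c_K == 0) return(0)
  w_end <- alpha_tilde / model$alpha
  if (w_end > 1) stop("alpha_tilde exceeds alpha")
  Ko0 <- model$ions$conc_out[i]; Ki0 <- model$ions$conc_in[i]
  alpha <- model$alpha
  w <- seq(w_end, 1, length.out = n_steps + 1)
  y <- (1 - w * alpha) / (1 - alpha)
  Ko <- c_K - (c_K - Ko0) / w
  Ki <- c_K - (c_K - Ki0) / y
  if (any(Ko <= 0) || any(Ki <= 0))
    stop(sprintf("[%s] is non-positive on the integration range", species))
  f <- model$constants$RT * 1e-3 * alpha * c_K * log(Ko / Ki)
  h <- (1 - w_end) / n_steps
  h * (sum(f) - (f[1] + f[n_steps + 1]) / 2)
}

#' Osmotic work along the isotonic path (closed form)
#'
#' Pressure-volume work done by each species in displacing the membrane as
#' the compartments change volume, i.e. `RT * integral(K dV)` over both
#' compartments in closed form. On the isotonic path the per-species values
#' are nonzero (K+ and the impermeant anions do osmotic work, Na+ and Cl-
#' receive it) but their sum vanishes identically: the energy moving water
#' into the neurons is supplied by the co-transported ions' gradients.
#'
#' @inheritParams mixing_work_closed
#' @param split Return the outer/inner compartment contributions separately?
#' @return Named vector (or two-column matrix if `split`) of energies,
#'   J per litre of tissue.
#' @examples
#' sum(osmotic_work(swell_model(), 0.1))  # 0
#' @export
osmotic_work <- function(model, alpha_tilde = model$equilibrium$omega,
                         species = NULL, split = FALSE) {
  stopifnot(inherits(model, "swell_model"))
  v <- volume_change(alpha_tilde, model$alpha)
  a <- .species_args(model)
  out <- .osmotic(model$constants, model$alpha, a$Ko0, a$Ki0,
                  v$w, v$y, model$plan$c_K, split = split)
  if (!is.null(species)) out <- if (split) out[species, , drop = FALSE] else out[species]
  out
}

.energy_breakdown <- function(model, scenario, alpha_tilde, mixing, osmotic) {
  structure(list(scenario = scenario, alpha_tilde = alpha_tilde,
                 species = model$ions$name,
                 mixing_work = mixing, osmotic_work = osmotic,
                 total_mixing = sum(mixing), total_osmotic = sum(osmotic)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("Energy breakdown (%s scenario, alpha_tilde = %.4f)\n",
              x$scenario, x$alpha_tilde))
  df <- data.frame(species = x$species,
                   mixing_J_per_l = round(x$mixing_work, 1),
                   osmotic_J_per_l = round(x$osmotic_work, 1))
  print(df, row.names = FALSE)
  cat(sprintf("Totals: mixing %.1f J/l, osmotic %.1f J/l\n",
              x$total_mixing, x$total_osmotic))
  invisible(x)
}

#' @export
as.data.frame.energy_breakdown <- function(x, ...) {
  data.frame(scenario = x$scenario, alpha_tilde = x$alpha_tilde,
             species = x$species,
             mixing_work_J_per_l = x$mixing_work,
             osmotic_work_J_per_l = x$osmotic_work)
}

#' Energy breakdown for the isotonic path
#'
#' @inheritParams mixing_work_closed
#' @return An `energy_breakdown` (scenario `"isotonic"`).
#' @examples
#' isotonic_energy(swell_model())
#' @export
isotonic_energy <- function(model, alpha_tilde = model$equilibrium$omega) {
  .energy_breakdown(model, "isotonic", alpha_tilde,
                    mixing_work_closed(model, alpha_tilde),
                    osmotic_work(model, alpha_tilde))
}

#' Complete mixing at constant volume
#'
#' Reference scenario: all species — including the impermeant anions, as if
#' they were made permeant — equilibrate to their volume-weighted mean
#' concentration at the unchanged physiological volumes (`w = y = 1`). The
#' final concentrations equal those of the full-equilibrium state, so the
#' total work equals the isotonic-path total; only its distribution over the
#' species differs. No osmotic work is done (the volume is fixed).
#'
#' @param model A [swell_model()].
#' @return An `energy_breakdown` (scenario `"isochoric"`).
#' @examples
#' isochoric_complete_mixing(swell_model())  # Na 80.3, K 66.8, ... J/l
#' @export
isochoric_complete_mixing <- function(model) {
  stopifnot(inherits(model, "swell_model"))
  a <- .species_args(model)
  alpha <- model$alpha
  Kbar <- alpha * a$Ko0 + (1 - alpha) * a$Ki0
  mixing <- model$constants$RT * 1e-3 *
    (alpha * .xlogx(a$Ko0) + (1 - alpha) * .xlogx(a$Ki0) - .xlogx(Kbar))
  .energy_breakdown(model, "isochoric", model$alpha, mixing, 0 * mixing)
}

#' Work of mixing toward a Donnan equilibrium
#'
#' Solves the Donnan state at `alpha_tilde` and evaluates the work done in
#' reaching it from the physiological state, with a transport concentration
#' recomputed per species from the endpoint conditions for this particular
#' final state (`c_K = (Ko0 - w KoDonnan)/(1 - w)`). At `alpha_tilde =
#' alpha` the transfer is isochoric (`w = y = 1`): the volume terms vanish
#' and no osmotic work is done.
#'
#' @param model A [swell_model()].
#' @param alpha_tilde Final extracellular volume fraction, in (0, `alpha`].
#' @return An `energy_breakdown` (scenario `"donnan"`).
#' @examples
#' work_to_donnan(swell_model(), 0.25)$total_mixing  # about 197 J/l
#' @export
work_to_donnan <- function(model, alpha_tilde) {
  stopifnot(inherits(model, "swell_model"))
  if (alpha_tilde <= 0 || alpha_tilde > model$alpha)
    stop("alpha_tilde must lie in (0, alpha]")
  d <- donnan_equilibrium(model, alpha_tilde)
  a <- .species_args(model)
  v <- volume_change(alpha_tilde, model$alpha)
  if (abs(v$w - 1) < 1e-12) {
    # isochoric transfer: the volume terms of the closed form vanish and the
    # work reduces to the chemical-potential drop
    if (any(d$state$conc_out < 0) || any(d$state$conc_in < 0))
      stop("final concentrations must be non-negative")
    mixing <- .chem_drop(model$constants, model$alpha, a$Ko0, a$Ki0,
                         d$state$conc_out, d$state$conc_in, 1, 1)
    mixing[!a$perm] <- 0
    return(.energy_breakdown(model, "donnan", alpha_tilde, mixing, 0 * mixing))
  }
  c_don <- (a$Ko0 - v$w * d$state$conc_out) / (1 - v$w)
  c_don[!a$perm] <- 0
  mixing <- .eq12(model$constants, model$alpha, a$Ko0, a$Ki0,
                  d$state$conc_out, d$state$conc_in, v$w, v$y, c_don, a$perm)
  osmotic <- .osmotic(model$constants, model$alpha, a$Ko0, a$Ki0,
                      v$w, v$y, c_don)
  .energy_breakdown(model, "donnan", alpha_tilde, mixing, osmotic)
}

#' Volume at which the isotonic path has done a prescribed amount of work
#'
#' Finds the extracellular volume fraction at which the cumulative total work
#' of mixing along the isotonic path equals a reference amount — by default
#' the work of isochoric mixing to the Donnan equilibrium at the
#' physiological volume (about 197 J/l, matched after the extracellular
#' space has shrunk by roughly half).
#'
#' @param model A [swell_model()].
#' @param target Reference work, J per litre of tissue; default as above.
#' @return The matching `alpha_tilde` (volume fraction).
#' @examples
#' find_equal_work_volume(swell_model())  # about 0.116
#' @export
find_equal_work_volume <- function(model, target = NULL) {
  stopifnot(inherits(model, "swell_model"))
  if (is.null(target)) target <- work_to_donnan(model, model$alpha)$total_mixing
  omega <- model$equilibrium$omega
  f <- function(a) sum(mixing_work_closed(model, a)) - target
  f_lo <- f(omega)
  if (abs(f_lo) < 1e-9) return(omega)
  if (f_lo < 0 || f(model$alpha) > 0)
    stop("no crossing of the target work in (omega, alpha)")
  stats::uniroot(f, c(omega, model$alpha), tol = .Machine$double.eps,
                 f.lower = f_lo)$root
}

#' Osmotic pressure equivalent of a concentration difference
#'
#' Van 't Hoff relation `Pi = R T delta_c` for an ideal solute difference
#' across a semi-permeable membrane. A 1 mM imbalance at 310 K corresponds
#' to about 2.58 kPa or 19.3 mmHg — more than the physiological intracranial
#' pressure.
#'
#' @param delta_c Concentration difference, mM (= mol m^-3).
#' @param constants A [swell_constants()].
#' @return List with `pascal` and `mmHg` (vectorised over `delta_c`).
#' @examples
#' vant_hoff_pressure(1)
#' @export
vant_hoff_pressure <- function(delta_c, constants = swell_constants()) {
  pa <- constants$RT * delta_c
  list(pascal = pa, mmHg = pa / constants$pascal_per_mmHg)
}

#' Water-to-ion transport stoichiometry
#'
#' For the total membrane transport to be isotonic, water must accompany the
#' ions at the ratio of the water molarity to the total transported solute
#' concentration (about 183 H2O per ion for a 304 mM total). If all water
#' instead passed through the carrier of a single species K, that carrier
#' would have to move `water_molarity / c_K` molecules per ion — about 458
#' per Cl- on the default plan, well within the capacity reported for the
#' KCC2 co-transporter.
#'
#' @param model A [swell_model()].
#' @return List with `overall` (H2O per transported solute particle) and
#'   `per_species` (H2O per ion if one carrier moved all water; `NA` for
#'   species with zero transport concentration).
#' @examples
#' water_per_ion(swell_model())
#' @export
water_per_ion <- function(model) {
  stopifnot(inherits(model, "swell_model"))
  c_K <- model$plan$c_K
  total <- sum(c_K[model$ions$permeant])
  if (total <= 0) stop("total transported concentration must be positive")
  water_mM <- model$constants$water_molarity * 1000
  per <- ifelse(c_K == 0, NA_real_, water_mM / c_K)
  names(per) <- names(c_K)
  list(overall = water_mM / total, per_species = per)
}
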