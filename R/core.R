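#' Physical constants for the swelling model
#'
#' Bundle of the physical constants used throughout the package. Defaults are
#' the values used for all reported numbers: the universal gas constant,
#' physiological temperature, the Faraday constant, the molar concentration of
#' pure water, and the pascal-per-mmHg conversion factor.
#'
#' @param gas_constant Universal gas constant R, J mol^-1 K^-1.
#' @param temperature Absolute temperature T, K.
#' @param faraday Faraday constant F, C mol^-1.
#' @param water_molarity Molarity of pure water, mol l^-1 (M).
#' @param pascal_per_mmHg Conversion factor, Pa per mmHg.
#'
#' @return An object of class `swell_constants`, a named list with the five
#'   fields above plus `RT` (J mol^-1) for convenience.
#' @examples
#' swell_constants()
#' swell_constants(temperature = 298)
#' @export
swell_constants <- function(gas_constant = 8.3145, temperature = 310,
                            faraday = 96485, water_molarity = 55.6,
                            pascal_per_mmHg = 133.322) {
  vals <- c(gas_constant = gas_constant, temperature = temperature,
            faraday = faraday, water_molarity = water_molarity,
            pascal_per_mmHg = pascal_per_mmHg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical constants must be finite and strictly positive")
  structure(list(gas_constant = gas_constant, temperature = temperature,
                 faraday = faraday, water_molarity = water_molarity,
                 pascal_per_mmHg = pascal_per_mmHg,
                 RT = gas_constant * temperature),
            class = "swell_constants")
}

#' Build a table of ion species
#'
#' An ion table describes every species in the two-compartment system: its
#' valence, whether it can permeate the neuronal membrane, and its initial
#' (physiological) concentration in the extracellular and intracellular
#' compartment. Impermeant species (the metabolite/macromolecule anions) may
#' be present on both sides; their two pools never exchange.
#'
#' @param name Character vector of species labels (unique).
#' @param valence Integer vector of signed charges.
#' @param permeant Logical vector; `FALSE` for confined species.
#' @param conc_out,conc_in Initial concentrations, mM (non-negative).
#'
#' @return A `data.frame` of class `ion_table`.
#' @seealso [physiological_ions()] for the packaged default table.
#' @examples
#' ion_table("Na", 1, TRUE, 148, 12)
#' @export
ion_table <- function(name, valence, permeant, conc_out, conc_in) {
  n <- length(name)
  if (anyDuplicated(name)) stop("ion species names must be unique")
  if (length(valence) != n || length(permeant) != n ||
      length(conc_out) != n || length(conc_in) != n)
    stop("all ion table columns must have the same length")
  if (any(valence != round(valence)) || any(valence == 0))
    stop("valences must be nonzero integers")
  if (any(conc_out < 0) || any(conc_in < 0))
    stop("concentrations must be non-negative")
  structure(data.frame(name = as.character(name),
                       valence = as.integer(valence),
                       permeant = as.logical(permeant),
                       conc_out = as.numeric(conc_out),
                       conc_in = as.numeric(conc_in),
                       stringsAsFactors = FALSE),
            class = c("ion_table", "data.frame"))
}

#' Physiological ion concentrations of brain tissue
#'
#' The default ion table of the model: the four permeant monovalent species
#' (Na+, K+, Cl-, HCO3-) plus the impermeant anions A- (negatively charged
#' metabolites and macromolecules, present at 10 mM outside and 134 mM inside
#' the neurons). Both sides total 304 mM (isotonic) and carry zero net charge
#' (electro-neutral). Divalent cations are excluded: their concentrations are
#' too low to matter for the energy balance and they require a separate pump.
#'
#' @return An [ion_table()] with five species.
#' @examples
#' physiological_ions()
#' @export
physiological_ions <- function() {
  ion_table(name     = c("Na", "K", "Cl", "HCO3", "A"),
            valence  = c(1L, 1L, -1L, -1L, -1L),
            permeant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
            conc_out = c(148, 4, 113, 29, 10),
            conc_in  = c(12, 140, 8, 10, 134))
}

#' Snapshot of the two-compartment system
#'
#' A tissue state records the extracellular volume fraction together with the
#' per-species concentration in each compartment, for a fixed total tissue
#' volume of 1 litre.
#'
#' @param ions An [ion_table()] (supplies names, valences, permeant flags).
#' @param alpha_tilde Extracellular volume fraction, strictly in (0, 1).
#' @param conc_out,conc_in Named or positional numeric vectors of
#'   concentrations (mM), one entry per species in `ions`.
#'
#' @return An object of class `tissue_state`.
#' @export
tissue_state <- function(ions, alpha_tilde, conc_out, conc_in) {
  stopifnot(inherits(ions, "ion_table"))
  if (!is.numeric(alpha_tilde) || length(alpha_tilde) != 1 ||
      alpha_tilde <= 0 || alpha_tilde >= 1)
    stop("alpha_tilde must be a single number in (0, 1)")
  conc_out <- .match_species(conc_out, ions$name)
  conc_in <- .match_species(conc_in, ions$name)
  if (any(conc_out < 0) || any(conc_in < 0))
    stop("concentrations must be non-negative")
  structure(list(ions = ions, alpha_tilde = alpha_tilde,
                 conc_out = conc_out, conc_in = conc_in,
                 total_volume = 1),
            class = "tissue_state")
}

.match_species <- function(x, species) {
  if (length(x) != length(species))
    stop("need one concentration per species")
  if (!is.null(names(x))) {
    if (!setequal(names(x), species)) stop("concentration names do not match species")
    x <- x[species]
  }
  x <- as.numeric(x)
  names(x) <- species
  x
}

#' Initial tissue state from an ion table
#'
#' @param ions An [ion_table()].
#' @param alpha Physiological extracellular volume fraction (default 0.25).
#' @return A [tissue_state()] holding the initial concentrations.
#' @export
initial_state <- function(ions = physiological_ions(), alpha = 0.25) {
  tissue_state(ions, alpha, ions$conc_out, ions$conc_in)
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("Tissue state (alpha_tilde = %.4f)\n", x$alpha_tilde))
  df <- data.frame(species = x$ions$name, valence = x$ions$valence,
                   conc_out = round(x$conc_out, 2),
                   conc_in = round(x$conc_in, 2))
  print(df, row.names = FALSE)
  cat(sprintf("Totals: outside %.2f mM, inside %.2f mM\n",
              total_concentration(x, "outside"),
              total_concentration(x, "inside")))
  invisible(x)
}

.side_conc <- function(state, side) {
  side <- match.arg(side, c("outside", "inside"))
  if (side == "outside") state$conc_out else state$conc_in
}

#' Total solute concentration on one side of the membrane
#'
#' @param state A [tissue_state()].
#' @param side `"outside"` or `"inside"`.
#' @return Total concentration in mM (arithmetic sum over species).
#' @examples
#' total_concentration(initial_state(), "outside")  # 304
#' @export
total_concentration <- function(state, side = c("outside", "inside")) {
  stopifnot(inherits(state, "tissue_state"))
  sum(.side_conc(state, match.arg(side)))
}

#' Signed, valence-weighted charge imbalance of one compartment
#'
#' Returns the net fixed-charge concentration sum(z_K [K]); zero for an
#' electro-neutral bulk solution.
#'
#' @inheritParams total_concentration
#' @return Net charge concentration, mM (signed).
#' @export
charge_imbalance <- function(state, side = c("outside", "inside")) {
  stopifnot(inherits(state, "tissue_state"))
  sum(state$ions$valence * .side_conc(state, match.arg(side)))
}

#' Per-species particle totals (conserved quantities)
#'
#' Amount of each species per litre of tissue,
#' `alpha_tilde * conc_out + (1 - alpha_tilde) * conc_in` (mmol per litre).
#' These totals are invariant along any path of the closed system.
#'
#' @param state A [tissue_state()].
#' @return Named numeric vector, mmol per litre of tissue.
#' @examples
#' particle_totals(initial_state())[["Na"]]  # 46
#' @export
particle_totals <- function(state) {
  stopifnot(inherits(state, "tissue_state"))
  state$alpha_tilde * state$conc_out + (1 - state$alpha_tilde) * state$conc_in
}

#' Audit a tissue state for tonicity and electro-neutrality
#'
#' Checks the two structural requirements of the model: both bulk solutions
#' are electro-neutral, and (optionally) the state is isotonic, i.e. the
#' total solute concentrations agree across the membrane.
#'
#' @param state A [tissue_state()].
#' @param tol Absolute tolerance, mM. Use the default `1e-9` for states the
#'   model computed itself; `0.1` is appropriate when auditing states rebuilt
#'   from rounded printed tables.
#' @param isotonic Also require equal totals across the membrane?
#' @return Invisibly, a named vector of residuals (mM); errors if any exceeds
#'   `tol`.
#' @export
audit_state <- function(state, tol = 1e-9, isotonic = TRUE) {
  res <- c(charge_out = charge_imbalance(state, "outside"),
           charge_in = charge_imbalance(state, "inside"),
           tonicity = if (isotonic)
             total_concentration(state, "outside") -
             total_concentration(state, "inside") else 0)
  bad <- abs(res) > tol
  if (any(bad))
    stop(sprintf("state audit failed: %s",
                 paste(sprintf("%s = %.3g mM", names(res)[bad], res[bad]),
                       collapse = ", ")))
  invisible(res)
}

#' Relative volume changes of the two compartments
#'
#' For an extracellular compartment shrinking from volume fraction `alpha` to
#' `alpha_tilde = w * alpha`, the intracellular compartment expands by
#' `y = (1 - w * alpha) / (1 - alpha)`. Volume is conserved:
#' `w * alpha + y * (1 - alpha) = 1`.
#'
#' @param alpha_tilde Running extracellular volume fraction.
#' @param alpha Initial (physiological) extracellular volume fraction.
#' @return List with elements `w` and `y`.
#' @export
volume_change <- function(alpha_tilde, alpha) {
  if (any(alpha_tilde <= 0)) stop("alpha_tilde must be positive")
  w <- alpha_tilde / alpha
  list(w = w, y = (1 - w * alpha) / (1 - alpha))
}
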