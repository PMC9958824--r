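# Scenario configuration and report writers. Data files are deterministic:
# fixed column order, "." decimal, no timestamps; concentrations rounded to
# 0.01 mM and energies to 0.1 J/l. A .log.json sidecar carries the config
# hash and the physical constants of the run.

#' Load a scenario configuration
#'
#' Reads a YAML or JSON scenario describing the ion table and the model
#' settings, validates it, and audits the ion table for electro-neutrality
#' and isotonicity before any computation. The packaged fixture
#' `"physiological"` reproduces the default brain-tissue table exactly.
#'
#' Schema (YAML shown; JSON is equivalent):
#' \preformatted{
#' alpha: 0.25          # extracellular volume fraction
#' temperature: 310     # K (optional, default 310)
#' ions:
#'   - {name: Na, valence: 1, permeant: true, conc_out: 148, conc_in: 12}
#'   - ...
#' c_override: {Na: 179.0, K: -27.0}   # optional transport-plan overrides
#' sweep: {from: 0.025, to: 0.25, step: 0.005}   # optional report grid
#' format: csv          # csv | json
#' }
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or the name of a
#'   packaged fixture (currently `"physiological"`).
#' @param audit_tol Tolerance (mM) for the electro-neutrality and isotonicity
#'   audits of the configured ion table.
#' @return Object of class `swell_scenario`: list with `ions` (an
#'   [ion_table()]), `alpha`, `constants`, `c_override`, `sweep`, `format`.
#' @examples
#' sc <- load_scenario("physiological")
#' sum(sc$ions$conc_out)  # 304
#' @export
load_scenario <- function(path, audit_tol = 1e-6) {
  if (identical(path, "physiological") || identical(path, "table1")) {
    path <- system.file("extdata", "physiological.yaml", package = "isoswell",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be a .yaml, .yml or .json file"))
  for (field in c("alpha", "ions"))
    if (is.null(raw[[field]])) stop(sprintf("config is missing field '%s'", field))
  ion_raw <- raw$ions
  if (is.data.frame(ion_raw)) ion_raw <- split(ion_raw, seq_len(nrow(ion_raw)))
  need <- c("name", "valence", "permeant", "conc_out", "conc_in")
  for (ion in ion_raw)
    for (f in need)
      if (is.null(ion[[f]]) || is.na(ion[[f]]))
        stop(sprintf("ion entry is missing field '%s'", f))
  ions <- ion_table(name = vapply(ion_raw, function(i) as.character(i$name), ""),
                    valence = vapply(ion_raw, function(i) as.numeric(i$valence), 0),
                    permeant = vapply(ion_raw, function(i) as.logical(i$permeant), NA),
                    conc_out = vapply(ion_raw, function(i) as.numeric(i$conc_out), 0),
                    conc_in = vapply(ion_raw, function(i) as.numeric(i$conc_in), 0))
  temperature <- if (is.null(raw$temperature)) 310 else as.numeric(raw$temperature)
  constants <- swell_constants(temperature = temperature)
  audit_state(initial_state(ions, as.numeric(raw$alpha)), tol = audit_tol,
              isotonic = TRUE)
  c_override <- NULL
  if (!is.null(raw$c_override)) c_override <- unlist(raw$c_override)
  sweep <- NULL
  if (!is.null(raw$sweep))
    sweep <- list(from = as.numeric(raw$sweep$from),
                  to = as.numeric(raw$sweep$to),
                  step = as.numeric(raw$sweep$step))
  structure(list(ions = ions, alpha = as.numeric(raw$alpha),
                 constants = constants, c_override = c_override,
                 sweep = sweep,
                 format = if (is.null(raw$format)) "csv" else raw$format),
            class = "swell_scenario")
}

#' Write a scenario configuration
#'
#' Serialises a scenario back to YAML or JSON (by file extension); a
#' write-then-load round trip reproduces the configuration.
#'
#' @param scenario A `swell_scenario` (see [load_scenario()]).
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "swell_scenario"))
  doc <- list(alpha = scenario$alpha,
              temperature = scenario$constants$temperature,
              ions = lapply(seq_len(nrow(scenario$ions)), function(i)
                as.list(scenario$ions[i, ])),
              format = scenario$format)
  if (!is.null(scenario$c_override)) doc$c_override <- as.list(scenario$c_override)
  if (!is.null(scenario$sweep)) doc$sweep <- scenario$sweep
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(doc, path)
  else if (ext == "json")
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else stop("path must end in .yaml, .yml or .json")
  invisible(path)
}

.scenario_model <- function(scenario) {
  swell_model(ions = scenario$ions, alpha = scenario$alpha,
              constants = scenario$constants,
              c_override = scenario$c_override)
}

.write_table <- function(df, path, format = "csv") {
  num <- vapply(df, is.numeric, NA)
  if (format == "json")
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  else utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

.run_log <- function(scenario, out_dir, command) {
  cfg <- tempfile(fileext = ".json")
  on.exit(unlink(cfg))
  write_scenario(scenario, cfg)
  log_path <- file.path(out_dir, paste0(command, ".log.json"))
  jsonlite::write_json(
    list(command = command,
         config_md5 = unname(tools::md5sum(cfg)),
         constants = unclass(scenario$constants)),
    log_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_path
}

.default_grid <- function(scenario, model) {
  if (!is.null(scenario$sweep))
    return(seq(scenario$sweep$from, scenario$sweep$to, by = scenario$sweep$step))
  seq(model$equilibrium$omega, model$alpha, length.out = 46)
}

#' Run a reporting command
#'
#' End-to-end report writer: builds the model from a scenario and emits the
#' canonical data tables.
#'
#' * `equilibrium` — the full-equilibrium concentrations and the transport
#'   plan, plus a JSON record of `w_e`, `omega`, `y`;
#' * `donnan` — the Donnan state at `alpha_tilde`, plus ratio/potential JSON;
#' * `path` — a concentration sweep along the isotonic path, with the
#'   conservation audit;
#' * `energy` — mixing/osmotic work per species for the isotonic and Donnan
#'   scenarios over the sweep grid;
#' * `figures` — the curve tables behind the package's standard figures
#'   (total concentrations and potentials, concentration-volume curves,
#'   inter-ion lines, and the six energy panels).
#'
#' @param command One of `"equilibrium"`, `"donnan"`, `"path"`, `"energy"`,
#'   `"figures"`.
#' @param scenario A `swell_scenario` (see [load_scenario()]) or a path/fixture
#'   name accepted by it.
#' @param out_dir Output directory (created if missing).
#' @param alpha_tilde Volume fraction for the `donnan` command.
#' @param grid Numeric vector of volume fractions for sweep commands;
#'   defaults to the scenario's `sweep` or 46 points on `[omega, alpha]`.
#' @param format `"csv"` (default) or `"json"` for the data tables.
#' @return Invisibly, a character vector of the files written.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' run_report("equilibrium", load_scenario("physiological"), dir)
#' @export
run_report <- function(command = c("equilibrium", "donnan", "path", "energy",
                                   "figures"),
                       scenario, out_dir = ".", alpha_tilde = NULL,
                       grid = NULL, format = NULL) {
  command <- match.arg(command)
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  stopifnot(inherits(scenario, "swell_scenario"))
  if (is.null(format)) format <- scenario$format
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  model <- .scenario_model(scenario)
  ext <- if (format == "json") ".json" else ".csv"
  files <- character(0)
  path_of <- function(stem) file.path(out_dir, paste0(stem, ext))

  if (command == "equilibrium") {
    eq <- model$equilibrium
    df <- data.frame(species = model$ions$name,
                     conc_out = round(model$ions$conc_out, 2),
                     conc_in = round(model$ions$conc_in, 2),
                     K_e = round(as.numeric(eq$K_e), 2),
                     c_K = round(as.numeric(model$plan$c_K), 2))
    files <- c(files, .write_table(df, path_of("equilibrium"), format))
    js <- file.path(out_dir, "equilibrium_summary.json")
    jsonlite::write_json(list(w_e = eq$w_e, omega = eq$omega, y = eq$y,
                              alpha_min = model$alpha_min),
                         js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, js)
  } else if (command == "donnan") {
    if (is.null(alpha_tilde)) alpha_tilde <- model$alpha
    d <- donnan_equilibrium(model, alpha_tilde)
    df <- data.frame(species = model$ions$name,
                     conc_out = round(as.numeric(d$state$conc_out), 2),
                     conc_in = round(as.numeric(d$state$conc_in), 2))
    files <- c(files, .write_table(df, path_of("donnan"), format))
    js <- file.path(out_dir, "donnan_summary.json")
    jsonlite::write_json(list(alpha_tilde = d$alpha_tilde, rho = d$rho,
                              potential_mV = d$potential,
                              total_imbalance_mM = donnan_total_imbalance(d)),
                         js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, js)
  } else if (command == "path") {
    if (is.null(grid)) grid <- .default_grid(scenario, model)
    pr <- predict(model, grid)
    pr$conc_out <- round(pr$conc_out, 2)
    pr$conc_in <- round(pr$conc_in, 2)
    files <- c(files, .write_table(pr, path_of("path"), format))
    aud <- audit_path(model, n_points = max(length(grid), 2),
                      from = min(grid), to = max(grid))
    js <- file.path(out_dir, "path_audit.json")
    jsonlite::write_json(list(pass = aud$pass, tol_mM = aud$tol,
                              max_residuals_mM = as.list(aud$max_residuals)),
                         js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, js)
  } else if (command == "energy") {
    if (is.null(grid)) grid <- .default_grid(scenario, model)
    rows <- lapply(grid, function(a)
      rbind(as.data.frame(isotonic_energy(model, a)),
            as.data.frame(work_to_donnan(model, a))))
    df <- do.call(rbind, rows)
    df$mixing_work_J_per_l <- round(df$mixing_work_J_per_l, 1)
    df$osmotic_work_J_per_l <- round(df$osmotic_work_J_per_l, 1)
    files <- c(files, .write_table(df, path_of("energy"), format))
  } else if (command == "figures") {
    if (is.null(grid)) grid <- .default_grid(scenario, model)
    files <- c(files, .figure_tables(model, grid, out_dir, format))
  }
  files <- c(files, .run_log(scenario, out_dir, command))
  invisible(files)
}

# curve tables behind the standard figures: totals/potentials, the
# concentration-volume curves for both scenarios, the inter-ion straight
# lines, and the six energy panels
.figure_tables <- function(model, grid, out_dir, format) {
  ext <- if (format == "json") ".json" else ".csv"
  perm <- model$ions$permeant
  pnames <- model$ions$name[perm]
  files <- character(0)

  tot <- do.call(rbind, lapply(grid, function(a) {
    s <- path_state(model, a)
    d <- donnan_equilibrium(model, a)
    vn <- nernst_potential(s$conc_out[perm], s$conc_in[perm],
                           model$ions$valence[perm], model$constants)
    row <- data.frame(alpha_tilde = a,
                      iso_total_out = total_concentration(s, "outside"),
                      iso_total_in = total_concentration(s, "inside"),
                      donnan_total_out = total_concentration(d$state, "outside"),
                      donnan_total_in = total_concentration(d$state, "inside"),
                      donnan_potential_mV = d$potential)
    for (k in seq_along(pnames))
      row[[paste0("nernst_", pnames[k], "_mV")]] <- vn[k]
    row
  }))
  tot[-1] <- lapply(tot[-1], round, 2)
  f <- file.path(out_dir, paste0("fig_totals_potentials", ext))
  files <- c(files, .write_table(tot, f, format))

  conc <- do.call(rbind, lapply(grid, function(a) {
    s <- path_state(model, a)
    d <- donnan_equilibrium(model, a)
    data.frame(alpha_tilde = a, species = model$ions$name,
               iso_out = round(as.numeric(s$conc_out), 2),
               iso_in = round(as.numeric(s$conc_in), 2),
               donnan_out = round(as.numeric(d$state$conc_out), 2),
               donnan_in = round(as.numeric(d$state$conc_in), 2))
  }))
  f <- file.path(out_dir, paste0("fig_concentrations", ext))
  files <- c(files, .write_table(conc, f, format))

  lines <- do.call(rbind, lapply(grid, function(a) {
    s <- path_state(model, a)
    data.frame(K_out = round(s$conc_out[["K"]], 2),
               Na_out = round(s$conc_out[["Na"]], 2),
               Cl_out = round(s$conc_out[["Cl"]], 2))
  }))
  if (all(c("K", "Na", "Cl") %in% model$ions$name)) {
    f <- file.path(out_dir, paste0("fig_interion", ext))
    files <- c(files, .write_table(lines, f, format))
  }

  energy <- do.call(rbind, lapply(grid, function(a) {
    iso <- isotonic_energy(model, a)
    don <- work_to_donnan(model, a)
    rbind(cbind(as.data.frame(iso),
                total_mixing = iso$total_mixing,
                total_osmotic = iso$total_osmotic),
          cbind(as.data.frame(don),
                total_mixing = don$total_mixing,
                total_osmotic = don$total_osmotic))
  }))
  num <- vapply(energy, is.numeric, NA)
  energy[num & names(energy) != "alpha_tilde"] <-
    lapply(energy[num & names(energy) != "alpha_tilde"], round, 1)
  f <- file.path(out_dir, paste0("fig_energy", ext))
  files <- c(files, .write_table(energy, f, format))
  files
}
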