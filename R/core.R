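# Configuration records shared by all stages. Internal units are seconds,
# micrometres and s^-1 rates throughout; milliseconds and nanometres appear
# only in reports and on-disk localisation tables.

#' Microscopic transition rates of the target-search cycle
#'
#' The linear state model 3D \eqn{\rightleftharpoons} 1D
#' \eqn{\rightleftharpoons} PAM (plus an absorbing target-bound state) is
#' parameterised by four first-order rates. `k_Target_to_3D` is fixed at 0 in
#' all standard analyses: once a complete R-loop forms, the nuclease is
#' treated as irreversibly bound.
#'
#' @param k_3D_to_1D,k_1D_to_3D,k_1D_to_PAM,k_PAM_to_1D transition rates
#'   (s^-1), all non-negative.
#' @param k_Target_to_3D unbinding rate from the target (s^-1); default 0.
#' @return A `kinetic_rates` object (named numeric vector).
#' @examples
#' kinetic_rates(20, 40, 100, 200)
#' @export
kinetic_rates <- function(k_3D_to_1D, k_1D_to_3D, k_1D_to_PAM, k_PAM_to_1D,
                          k_Target_to_3D = 0) {
  x <- c(k_3D_to_1D = k_3D_to_1D, k_1D_to_3D = k_1D_to_3D,
         k_1D_to_PAM = k_1D_to_PAM, k_PAM_to_1D = k_PAM_to_1D,
         k_Target_to_3D = k_Target_to_3D)
  stopifnot(is.numeric(x), length(x) == 5L, !anyNA(x))
  structure(x, class = "kinetic_rates")
}

#' Apparent diffusion coefficients of the four states
#'
#' 1D sliding and PAM investigation cover distances well below the
#' localisation precision at 10 ms framing, so `D_1D` and `D_PAM` default to
#' exactly 0; they remain configurable. The target-bound state moves with the
#' plasmid it is bound to (default 0.21 um^2/s).
#'
#' @param D_3D free 3D diffusion coefficient (um^2/s).
#' @param D_1D,D_PAM,D_Target diffusion coefficients of the DNA-associated
#'   states (um^2/s).
#' @return A `state_diffusion` object.
#' @seealso [diffusion_preset()]
#' @export
state_diffusion <- function(D_3D = 2.0, D_1D = 0, D_PAM = 0, D_Target = 0.21) {
  x <- c(D_3D = D_3D, D_1D = D_1D, D_PAM = D_PAM, D_Target = D_Target)
  stopifnot(is.numeric(x), length(x) == 4L, !anyNA(x))
  structure(x, class = "state_diffusion")
}

#' Built-in diffusion presets
#'
#' Two presets differing only in `D_3D`: 2.0 um^2/s for Cas9-class nucleases
#' and 2.2 um^2/s for Cas12a-class nucleases (hydrodynamic-radius based
#' constants, taken as given).
#'
#' @param class `"cas9-class"` or `"cas12a-class"`.
#' @return A `state_diffusion` object.
#' @export
diffusion_preset <- function(class = c("cas9-class", "cas12a-class")) {
  class <- match.arg(class)
  state_diffusion(D_3D = if (class == "cas9-class") 2.0 else 2.2)
}

#' Cell geometry: spherocylinder
#'
#' A cylinder of the given length capped by two hemispheres of the given
#' radius, the standard approximation of an *E. coli* cell.
#'
#' @param cylinder_length length of the cylindrical part (um).
#' @param radius radius of the cylinder and caps (um).
#' @return A `cell_geometry` object.
#' @export
cell_geometry <- function(cylinder_length = 2.0, radius = 0.5) {
  stopifnot(cylinder_length > 0, radius > 0)
  structure(list(cylinder_length = cylinder_length, radius = radius),
            class = "cell_geometry")
}

#' Total volume of a spherocylinder
#' @param geometry a [cell_geometry()].
#' @return Volume in um^3.
#' @export
cell_volume <- function(geometry) {
  r <- geometry$radius
  pi * r^2 * geometry$cylinder_length + 4 / 3 * pi * r^3
}

#' Imaging and discretisation configuration
#'
#' Frame interval, simulation over-sampling step, localisation uncertainty,
#' burn-in, the truncated-exponential track-length law, and the histogram
#' binning of apparent diffusion coefficients.
#'
#' @param frame_interval camera frame interval (s).
#' @param t_step simulation sub-step; must divide `frame_interval` evenly (s).
#' @param sigma_loc per-coordinate localisation uncertainty (um).
#' @param equilibration burn-in simulated before the first localisation (s).
#'   Initial states/positions are drawn from the stationary law, so this only
#'   guards against initialisation artefacts; it can be shortened for speed.
#' @param mean_track_steps target mean of the truncated-exponential
#'   track-length law (steps).
#' @param min_track_steps,max_track_steps support of the track-length law.
#' @param hist_bins,hist_min,hist_max histogram binning: number of
#'   logarithmic bins and range (um^2/s).
#' @return An `imaging_config` object.
#' @export
imaging_config <- function(frame_interval = 0.010, t_step = 0.0001,
                           sigma_loc = 0.035, equilibration = 0.200,
                           mean_track_steps = 3, max_track_steps = 8,
                           min_track_steps = 1, hist_bins = 85,
                           hist_min = 0.04, hist_max = 10) {
  structure(list(frame_interval = frame_interval, t_step = t_step,
                 sigma_loc = sigma_loc, equilibration = equilibration,
                 mean_track_steps = mean_track_steps,
                 max_track_steps = max_track_steps,
                 min_track_steps = min_track_steps,
                 hist_bins = hist_bins, hist_min = hist_min,
                 hist_max = hist_max),
            class = "imaging_config")
}

#' Genome and plasmid model for PAM-density calculations
#'
#' Defaults describe the experimental background: an *E. coli* K-12 class
#' genome (4,641,652 bp, GC 50.5%) at an average copy number of 2.3 and a
#' high-copy target plasmid (64 copies). `n_targets` is the number of
#' protospacer sites to find.
#'
#' @param genome_length genome size (bp).
#' @param genome_copy average genome copy number (dimensionless).
#' @param gc_content genomic GC fraction in (0, 1).
#' @param plasmid_length,plasmid_copy plasmid size (bp) and copy number.
#' @param n_targets number of target sites.
#' @return A `genome_model` object.
#' @export
genome_model <- function(genome_length = 4641652, genome_copy = 2.3,
                         gc_content = 0.505, plasmid_length = 2500,
                         plasmid_copy = 64, n_targets = 1) {
  stopifnot(gc_content > 0, gc_content < 1, genome_copy > 0,
            plasmid_copy >= 0, n_targets >= 0)
  structure(list(genome_length = genome_length, genome_copy = genome_copy,
                 gc_content = gc_content, plasmid_length = plasmid_length,
                 plasmid_copy = plasmid_copy, n_targets = n_targets),
            class = "genome_model")
}

#' PAM motif specification
#'
#' One or more IUPAC-coded motifs (e.g. `"NGG"` for SpyCas9, `"TTTV"` for
#' LbCas12a, `"NNN"` for the PAM-relaxed SpRY variant, or the four-motif set
#' `c("TNTN", "TACV", "TTCV", "CTCV")` for relaxed Cas12a variants). The
#' motif set must be non-overlapping in match space (checked by enumeration)
#' so that motif densities are additive.
#'
#' @param motifs character vector of IUPAC motifs, all of the same length.
#' @return A `pam_spec` object.
#' @export
pam_spec <- function(motifs) {
  stopifnot(is.character(motifs), length(motifs) >= 1)
  motifs <- toupper(motifs)
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", motifs)
  if (any(bad)) {
    stop("invalid IUPAC character in motif(s): ",
         paste(motifs[bad], collapse = ", "))
  }
  if (length(unique(nchar(motifs))) != 1) {
    stop("all motifs in a PAM set must have the same length")
  }
  expanded <- unlist(lapply(motifs, iupac_expand))
  if (anyDuplicated(expanded)) {
    stop("PAM motif set is overlapping in match space")
  }
  structure(list(motifs = motifs), class = "pam_spec")
}

#' Built-in PAM presets
#'
#' `"spycas9"` (NGG), `"spry"` (NNN), `"lbcas12a"` (TTTV) and `"implb"`
#' (TNTN/TACV/TTCV/CTCV). Presets fix the PAM motif set and D_3D only;
#' kinetic rates must be supplied by the user.
#'
#' @param preset preset name.
#' @return List with elements `pam` ([pam_spec()]) and `diffusion`
#'   ([state_diffusion()]).
#' @export
nuclease_preset <- function(preset = c("spycas9", "spry", "lbcas12a", "implb")) {
  preset <- match.arg(preset)
  pam <- switch(preset,
    spycas9 = pam_spec("NGG"),
    spry = pam_spec("NNN"),
    lbcas12a = pam_spec("TTTV"),
    implb = pam_spec(c("TNTN", "TACV", "TTCV", "CTCV")))
  diffusion <- diffusion_preset(
    if (preset %in% c("spycas9", "spry")) "cas9-class" else "cas12a-class")
  list(pam = pam, diffusion = diffusion)
}

#' Target-search simulation parameters
#'
#' @param p_dis probability of dissociating from DNA per 1D sliding episode
#'   without encountering a PAM; derived from the ~3 bp sliding length and
#'   held at 0.144 for all nucleases. Feeds the derivation of `n_1D_pam`; it
#'   does not enter the simulator directly.
#' @param n_1D_pam expected number of PAM motifs encountered per 1D sliding
#'   episode (dimensionless).
#' @param n_cells number of cells per ensemble.
#' @param n_repeats number of independent ensembles averaged.
#' @param t_max simulated horizon (s).
#' @param n_units nuclease copies per cell.
#' @param trial_mode where the target-encounter Bernoulli trial is applied:
#'   once per 1D episode (3D to 1D entry) or once per PAM visit.
#' @return A `search_params` object.
#' @export
search_params <- function(p_dis = 0.144, n_1D_pam = 1, n_cells = 2000,
                          n_repeats = 10, t_max = 86400, n_units = 1,
                          trial_mode = c("per-episode", "per-pam-visit")) {
  stopifnot(p_dis >= 0, p_dis <= 1, n_1D_pam > 0, n_cells >= 1,
            n_repeats >= 1, t_max >= 0, n_units >= 1)
  structure(list(p_dis = p_dis, n_1D_pam = n_1D_pam, n_cells = n_cells,
                 n_repeats = n_repeats, t_max = t_max, n_units = n_units,
                 trial_mode = match.arg(trial_mode)),
            class = "search_params")
}

#' Validate a joint configuration
#'
#' Checks every type invariant of the kinetic rates, state diffusion
#' coefficients, and imaging configuration. With `action = "error"` an
#' invalid configuration aborts with all violations listed; with
#' `action = "report"` the violations are returned as a character vector for
#' programmatic use.
#'
#' @param rates a [kinetic_rates()].
#' @param diffs a [state_diffusion()].
#' @param imaging an [imaging_config()].
#' @param action `"error"` to stop on violations, `"report"` to return them.
#' @return The configuration (list of the three records), invisibly, when
#'   valid; otherwise a character vector of violations (`"report"`) or an
#'   error (`"error"`).
#' @examples
#' validate_config(kinetic_rates(20, 40, 100, 200), state_diffusion(),
#'                 imaging_config())
#' @export
validate_config <- function(rates, diffs, imaging,
                            action = c("error", "report")) {
  action <- match.arg(action)
  v <- character()
  if (any(unclass(rates) < 0)) {
    v <- c(v, sprintf("negative rate: %s",
                      paste(names(rates)[rates < 0], collapse = ", ")))
  }
  if (rates[["k_1D_to_PAM"]] > 0 && rates[["k_PAM_to_1D"]] <= 0) {
    v <- c(v, "absorbing PAM state: k_PAM_to_1D must be > 0 when k_1D_to_PAM > 0")
  }
  if (any(unclass(diffs) < 0)) {
    v <- c(v, sprintf("negative diffusion coefficient: %s",
                      paste(names(diffs)[diffs < 0], collapse = ", ")))
  }
  ratio <- imaging$frame_interval / imaging$t_step
  if (abs(ratio - round(ratio)) > 1e-9 * ratio) {
    v <- c(v, "t_step does not divide frame_interval")
  }
  if (imaging$t_step <= 0) v <- c(v, "t_step must be positive")
  if (imaging$hist_min >= imaging$hist_max) {
    v <- c(v, "inverted histogram bounds: hist_min must be below hist_max")
  }
  if (imaging$mean_track_steps < imaging$min_track_steps ||
      imaging$mean_track_steps > imaging$max_track_steps) {
    v <- c(v, "mean_track_steps outside [min_track_steps, max_track_steps]")
  }
  if (imaging$sigma_loc < 0) v <- c(v, "negative sigma_loc")
  if (imaging$equilibration < 0) v <- c(v, "negative equilibration")
  if (length(v)) {
    if (action == "error") {
      stop("invalid configuration:\n  - ", paste(v, collapse = "\n  - "))
    }
    return(v)
  }
  invisible(list(rates = rates, diffusion = diffs, imaging = imaging))
}

#' Read / write configuration files
#'
#' Configurations are stored as YAML with one section per record
#' (`rates`, `diffusion`, `imaging`, `geometry`, `genome`, `pam`, `search`);
#' every field is optional and falls back to the documented default, so an
#' empty file yields the default configuration.
#'
#' @param path file path.
#' @return `read_config()`: a named list of configuration records.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build <- function(section, ctor) do.call(ctor, as.list(raw[[section]]))
  rates <- if (is.null(raw$rates)) NULL else build("rates", kinetic_rates)
  cfg <- list(
    rates = rates,
    diffusion = build("diffusion", state_diffusion),
    imaging = build("imaging", imaging_config),
    geometry = build("geometry", cell_geometry),
    genome = build("genome", genome_model),
    pam = if (is.null(raw$pam)) pam_spec("NGG") else build("pam", pam_spec),
    search = build("search", search_params))
  cfg
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(rates = NULL, diffusion = state_diffusion(), imaging = imaging_config(),
       geometry = cell_geometry(), genome = genome_model(),
       pam = pam_spec("NGG"), search = search_params())
}

#' @rdname read_config
#' @param config a named list of configuration records as returned by
#'   [read_config()].
#' @return `write_config()`: the path, invisibly.
#' @export
write_config <- function(config, path) {
  as_plain <- function(x) {
    if (is.null(x)) return(NULL)
    out <- as.list(unclass(x))
    lapply(out, function(v) if (is.numeric(v) || is.character(v)) v else v)
  }
  yaml::write_yaml(lapply(config, as_plain), path)
  invisible(path)
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat("Kinetic rates (s^-1):\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' @export
print.state_diffusion <- function(x, ...) {
  cat("State diffusion coefficients (um^2/s):\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

# Expand one IUPAC motif into its explicit DNA matches.
iupac_expand <- function(motif) {
  map <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  parts <- map[strsplit(motif, "")[[1]]]
  if (any(vapply(parts, is.null, logical(1)))) {
    stop("invalid IUPAC character in motif ", motif)
  }
  apply(expand.grid(parts, stringsAsFactors = FALSE), 1, paste0, collapse = "")
}
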