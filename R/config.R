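#' Simulation configuration
#'
#' Builds the full coefficient set of the model with literature defaults.
#' Every quantity the simulator uses is held here so that a run is fully
#' determined by a `sim_config` plus an RNG seed.
#'
#' Units: lengths in um, times in hours unless the name says otherwise,
#' concentrations in mmol/l, rates in per-minute. One iteration is 30
#' simulated minutes (`dt_min`).
#'
#' Key defaults and their origin:
#' \itemize{
#'   \item Promoter coefficients `delta` (10), `phi` (0.4), `eta` (1), `xi` (1);
#'     transcription `Phi` (5); translation `Omega` (5); per-cell synthesis cap
#'     `synthesis_cap` (200 mmol/l per 30 min).
#'   \item Deposition fractions `alpha_pm` 0.90 (provisional matrix) and
#'     `alpha_sm`/`alpha_bm` 0.01; activation fraction `kappa` 0.90; latent and
#'     active TGF-beta1 lifetime `tgfb_lifetime_h` 48 h.
#'   \item Division probability table `dp_*` (0.90 / 0.40 / 0.05 / 0.02 / 0.01);
#'     endosomal-complex inhibition coefficient `lambda_inhib` (0.1 per mmol/l);
#'     cell cycle `cycle_length_h` 24 h.
#'   \item Bond coefficient `Pi` 0.5 with default bond strengths `ccb0`, `csb0`
#'     = 1; bond interaction range `bond_range` 5 um (surface gap).
#'   \item TA migration speed `migration_speed` 1 um/min, provisional-matrix
#'     bias `p_bias` 0.8 within `sensing_radius` 60 um.
#'   \item Trafficking rates `k_*`, `prod_r1`, `prod_r2`: chosen so the
#'     normal-condition receptor distribution (20 mmol/l membrane, 10 mmol/l
#'     endosome) is a rest state of the constitutive cycle; see the methods
#'     vignette.
#' }
#'
#' @param ... name = value overrides of any default listed by
#'   `sim_config_defaults()`. Unknown names are an error.
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_seed_stem = 10)
#' cfg$alpha_pm
sim_config <- function(...) {
  defaults <- sim_config_defaults()
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("sim_config(): all overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("sim_config(): unknown configuration keys: ",
           paste(unknown, collapse = ", "))
    }
    defaults[names(overrides)] <- overrides
  }
  validate_sim_config(structure(defaults, class = "sim_config"))
}

#' Default configuration values
#'
#' @return Named list of every configuration key with its default.
#' @export
sim_config_defaults <- function() {
  list(
    # -- world geometry --
    lx = 100, ly = 100, wall_height = 100, tile_side = 20,
    n_seed_stem = 30,
    dt_min = 30,

    # -- promoter / expression (per-cell TGF-beta1 synthesis) --
    delta = 10, phi = 0.4, eta = 1, xi = 1,
    Phi = 5, Omega = 5, synthesis_cap = 200,
    strat_threshold = 10,      # um; D >= threshold counts as stratified
    strat_persist_h = 6,       # sustained stratification before differentiation

    # -- ECM deposition / activation / lifetime / remodeling --
    alpha_pm = 0.90, alpha_sm = 0.01, alpha_bm = 0.01,
    kappa = 0.90,
    tgfb_lifetime_h = 48,
    remodel_rate = 0.01,       # ECM_value decrement per contacting cell per iteration

    # -- trafficking network rates (per minute; k_bind per (mmol/l)^2 per minute) --
    k_bind = 0.001,
    k_int_complex = 1 / 3,
    k_int_receptor = 0.1,
    k_recycle = 0.15,
    k_deg_complex = 0.25,
    k_deg_receptor = 0.05,
    prod_r1 = 0.5, prod_r2 = 0.5,
    ode_rtol = 1e-9, ode_atol = 1e-12,

    # -- division --
    dp_on_pm_or_wound = 0.90,
    dp_normal = 0.40,
    dp_stratified_ta_wound = 0.05,
    dp_contact_ta = 0.02,
    dp_contact_stem = 0.01,
    lambda_inhib = 0.1,
    cycle_length_h = 24,
    contact_inhibit_neighbors = 10,
    contact_radius = 12,       # um centre distance for neighbourhood queries
    overlap_inhibit = 1.0,     # um sustained residual overlap => arrest
    overlap_persist_h = 3,

    # -- differentiation --
    colony_size_threshold = 120,
    colony_edge_neighbors = 4, # stem with < this many stem neighbours is on the edge
    ta_distance_threshold = 20,
    committed_dwell_h = 48,
    corneocyte_dwell_h = Inf,  # timed desquamation off; any finite value enables

    # -- migration --
    migration_speed = 1,       # um/min
    p_bias = 0.8,
    sensing_radius = 60,

    # -- bonds --
    Pi = 0.5, ccb0 = 1, csb0 = 1, bond_range = 5,

    # -- physics --
    k_rep = 1.0, k_att = 0.1, mobility = 0.5,
    k_settle = 0.2, stem_anchor = 20, phys_tol = 0.01, max_sweeps = 300,

    # -- run control --
    plateau_window = 200, plateau_frac = 0.02
  )
}

validate_sim_config <- function(cfg) {
  may_be_inf <- "corneocyte_dwell_h"  # Inf disables timed desquamation
  num1 <- function(key) {
    v <- cfg[[key]]
    ok <- is.numeric(v) && length(v) == 1L &&
      (is.finite(v) || (key %in% may_be_inf && is.infinite(v) && v > 0))
    if (!ok) stop("sim_config: '", key, "' must be a single finite number")
    v
  }
  for (key in names(cfg)) num1(key)

  fracs <- c("alpha_pm", "alpha_sm", "alpha_bm", "kappa", "p_bias",
             "dp_on_pm_or_wound", "dp_normal", "dp_stratified_ta_wound",
             "dp_contact_ta", "dp_contact_stem", "plateau_frac")
  for (key in fracs) {
    if (cfg[[key]] < 0 || cfg[[key]] > 1) {
      stop("sim_config: '", key, "' must lie in [0, 1]")
    }
  }
  nonneg <- c("delta", "phi", "eta", "xi", "Phi", "Omega", "synthesis_cap",
              "remodel_rate", "k_bind", "k_int_complex", "k_int_receptor",
              "k_recycle", "k_deg_complex", "k_deg_receptor", "prod_r1",
              "prod_r2", "lambda_inhib", "Pi", "migration_speed")
  for (key in nonneg) {
    if (cfg[[key]] < 0) stop("sim_config: '", key, "' must be >= 0")
  }
  pos <- c("lx", "ly", "wall_height", "tile_side", "dt_min", "tgfb_lifetime_h",
           "cycle_length_h", "committed_dwell_h", "corneocyte_dwell_h",
           "bond_range", "ccb0", "csb0", "k_rep", "k_att", "mobility",
           "phys_tol", "max_sweeps", "plateau_window", "ode_rtol", "ode_atol")
  for (key in pos) {
    if (cfg[[key]] <= 0) stop("sim_config: '", key, "' must be > 0")
  }
  if (cfg$n_seed_stem < 0 || cfg$n_seed_stem != round(cfg$n_seed_stem)) {
    stop("sim_config: 'n_seed_stem' must be a non-negative integer")
  }
  for (key in c("lx", "ly")) {
    if (abs(cfg[[key]] / cfg$tile_side - round(cfg[[key]] / cfg$tile_side)) > 1e-9) {
      stop("sim_config: '", key, "' must be a positive multiple of tile_side")
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", length(x), " parameters\n", sep = "")
  cat("  world: ", x$lx, " x ", x$ly, " um, wall ", x$wall_height,
      " um, ", x$n_seed_stem, " seed stem cells\n", sep = "")
  cat("  expression: delta=", x$delta, " phi=", x$phi, " Phi=", x$Phi,
      " Omega=", x$Omega, " cap=", x$synthesis_cap, "/30min\n", sep = "")
  cat("  ECM: alpha(PM)=", x$alpha_pm, " alpha(SM/BM)=", x$alpha_sm,
      " kappa=", x$kappa, " lifetime=", x$tgfb_lifetime_h, "h\n", sep = "")
  invisible(x)
}

# Number of 30-min iterations a TGF-beta1 parcel survives.
lifetime_iterations <- function(cfg) {
  as.integer(round(cfg$tgfb_lifetime_h * 60 / cfg$dt_min))
}

#' Write a configuration to a flat key/value text file
#'
#' One `key = value` pair per line; values are written with full double
#' precision so that a write/read round trip reproduces the configuration
#' bit-identically.
#'
#' @param cfg A [sim_config()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  lines <- vapply(names(cfg), function(k) {
    sprintf("%s = %.17g", k, cfg[[k]])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration from a flat key/value text file
#'
#' Unknown keys are an error, as are malformed lines. Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path File written by [write_sim_config()] (or by hand).
#' @return A validated [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(\\S+)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("read_sim_config(): malformed line(s): ",
         paste(lines[bad], collapse = "; "))
  }
  keys <- vapply(m, `[[`, character(1), 2L)
  vals <- as.numeric(vapply(m, `[[`, character(1), 3L))
  if (anyNA(vals)) stop("read_sim_config(): non-numeric value(s)")
  if (anyDuplicated(keys)) stop("read_sim_config(): duplicated key(s)")
  do.call(sim_config, as.list(setNames(vals, keys)))
}

#' Stable hash of a configuration
#'
#' 64-bit FNV-1a over the canonical serialized text, reported as 16 hex
#' characters. Used to stamp run records so replays can be matched to the
#' exact parameter set.
#'
#' @param cfg A [sim_config()] object.
#' @return A 16-character hex string.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  txt <- paste(vapply(names(cfg), function(k) sprintf("%s=%.17g", k, cfg[[k]]),
                      character(1)), collapse = ";")
  fnv1a64(txt)
}

# FNV-1a over UTF-8 bytes, done in two 32-bit halves to stay in double range.
fnv1a64 <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  fnv1a64_cpp(bytes)
}
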