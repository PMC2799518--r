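#' Matrix-class weights of a tile
#'
#' Maps a tile's `ECM_value` onto the three matrix-class signals the promoter
#' responds to. The classification bands are: basement membrane (BM) below 0.1,
#' secondary matrix (SM) in [0.1, 0.5), provisional matrix (PM) at and above
#' 0.5. At most one of the three weights is nonzero: `BM` is the indicator of
#' the BM band, while `SM` and `PM` carry the ECM_value itself inside their
#' bands (a partially remodeled tile signals proportionally less).
#'
#' @param ecm_value Numeric vector in [0, 1].
#' @return A data.frame with columns `PM`, `SM`, `BM` (one row per input).
#' @export
#' @examples
#' tile_weights(c(0, 0.3, 1))
tile_weights <- function(ecm_value) {
  if (!is.numeric(ecm_value)) stop("tile_weights(): ecm_value must be numeric")
  if (any(!is.finite(ecm_value)) || any(ecm_value < 0) || any(ecm_value > 1)) {
    stop("tile_weights(): ecm_value must lie in [0, 1]")
  }
  bm <- as.numeric(ecm_value < 0.1)
  sm <- ifelse(ecm_value >= 0.1 & ecm_value < 0.5, ecm_value, 0)
  pm <- ifelse(ecm_value >= 0.5, ecm_value, 0)
  data.frame(PM = pm, SM = sm, BM = bm)
}

# Tile class code (BM/SM/PM) from ECM_value; same bands as tile_weights().
tile_class <- function(ecm_value) {
  ifelse(ecm_value >= 0.5, TILE_CLASS_CODES[["PM"]],
         ifelse(ecm_value >= 0.1, TILE_CLASS_CODES[["SM"]],
                TILE_CLASS_CODES[["BM"]]))
}

#' TGF-beta1 promoter activity
#'
#' Promoter activity rises with three wound-associated signals: contact with
#' provisional or secondary matrix, active ligand-receptor complex on the
#' plasma membrane (LRCP), and stratification (height D at or above
#' `strat_threshold`, default 10 um). Contact with basement membrane fully
#' suppresses expression. The functional form is
#' \deqn{PRO = (1 - BM) (\delta (\xi PM + \eta SM) + \phi LRCP + D_w)}
#' with \eqn{D_w = 1} when `D >= strat_threshold`, and the matrix weights
#' zeroed when the cell is not in contact with a tile.
#'
#' @param weights A data.frame from [tile_weights()] (columns `PM`,`SM`,`BM`).
#' @param contact Logical; is the cell in contact with its tile?
#' @param LRCP Membrane ligand-receptor complex, mmol/l (>= 0).
#' @param D Stratification distance (height of the cell centre), um (>= 0).
#' @param config A [sim_config()].
#' @return Numeric vector of promoter activities (>= 0).
#' @export
#' @examples
#' cfg <- sim_config()
#' promoter_activity(tile_weights(1), TRUE, 0, 0, cfg)    # 10: PM contact
#' promoter_activity(tile_weights(0), TRUE, 20, 0, cfg)   # 0: BM suppression
promoter_activity <- function(weights, contact, LRCP, D, config = sim_config()) {
  if (any(LRCP < 0) || any(D < 0)) {
    stop("promoter_activity(): LRCP and D must be >= 0")
  }
  n <- max(nrow(weights), length(contact), length(LRCP), length(D))
  pm <- rep_len(weights$PM, n); sm <- rep_len(weights$SM, n)
  bm <- rep_len(weights$BM, n)
  contact <- rep_len(as.logical(contact), n)
  LRCP <- rep_len(LRCP, n); D <- rep_len(D, n)
  pm[!contact] <- 0; sm[!contact] <- 0; bm[!contact] <- 0
  d_w <- as.numeric(D >= config$strat_threshold)
  (1 - bm) * (config$delta * (config$xi * pm + config$eta * sm) +
                config$phi * LRCP + d_w)
}

#' Transcription and capped translation
#'
#' `mRNA = Phi * PRO` and `latent = min(Omega * mRNA, synthesis_cap)`: linear
#' below the per-cell synthesis ceiling (200 mmol/l per 30-minute iteration by
#' default), exactly the ceiling above it.
#'
#' @param PRO Promoter activity (>= 0), vectorised.
#' @param config A [sim_config()].
#' @return A list with numeric vectors `mRNA` and `latent`.
#' @export
#' @examples
#' transcribe_translate(1)    # mRNA 5, latent 25
#' transcribe_translate(100)  # capped at 200
transcribe_translate <- function(PRO, config = sim_config()) {
  if (any(PRO < 0)) stop("transcribe_translate(): PRO must be >= 0")
  mRNA <- config$Phi * PRO
  latent <- pmin(config$Omega * mRNA, config$synthesis_cap)
  list(mRNA = mRNA, latent = latent)
}

#' Trafficking rate parameters
#'
#' Rate constants of the ligand-receptor trafficking network (per minute;
#' `k_bind` per (mmol/l)^2 per minute). Defaults come from the active
#' [sim_config()]; see the methods vignette for the rationale.
#'
#' @param config A [sim_config()] supplying defaults.
#' @param ... name = value overrides of individual rates.
#' @return An object of class `trafficking_params`.
#' @export
trafficking_params <- function(config = sim_config(), ...) {
  p <- list(
    k_bind = config$k_bind,
    k_int_complex = config$k_int_complex,
    k_int_receptor = config$k_int_receptor,
    k_recycle = config$k_recycle,
    k_deg_complex = config$k_deg_complex,
    k_deg_receptor = config$k_deg_receptor,
    prod_r1 = config$prod_r1,
    prod_r2 = config$prod_r2
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) {
    stop("trafficking_params(): unknown rate(s): ", paste(unknown, collapse = ", "))
  }
  p[names(overrides)] <- overrides
  for (k in names(p)) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || !is.finite(p[[k]]) ||
        p[[k]] < 0) {
      stop("trafficking_params(): '", k, "' must be a single number >= 0")
    }
  }
  structure(p, class = "trafficking_params")
}

SPECIES <- c("ligand", "R1", "R2", "LRCP", "LRCE", "R1E", "R2E")

#' A subcellular state
#'
#' Convenience constructor for a single cell's trafficking species vector.
#' Defaults are the normal-condition concentrations (Table of initial
#' concentrations): R1 = R2 = 20, R1E = R2E = 10 mmol/l, ligand 10, no
#' complexes. `wound_start_state()` returns the wound-onset column: LRCP =
#' LRCE = 20, ligand = 100, receptors unchanged.
#'
#' @param ligand,R1,R2,LRCP,LRCE,R1E,R2E Concentrations in mmol/l.
#' @return Named numeric vector over the seven trafficking species.
#' @export
subcellular_state <- function(ligand = 10, R1 = 20, R2 = 20, LRCP = 0,
                              LRCE = 0, R1E = 10, R2E = 10) {
  v <- c(ligand = ligand, R1 = R1, R2 = R2, LRCP = LRCP, LRCE = LRCE,
         R1E = R1E, R2E = R2E)
  if (any(v < 0)) stop("subcellular_state(): concentrations must be >= 0")
  v
}

#' @rdname subcellular_state
#' @export
wound_start_state <- function() {
  subcellular_state(ligand = 100, R1 = 20, R2 = 20, LRCP = 20, LRCE = 20,
                    R1E = 10, R2E = 10)
}

#' Advance the trafficking network one iteration
#'
#' Integrates the mass-action ligand-receptor network over `dt_min` minutes
#' (30 by default). The network is: trimolecular binding
#' `ligand + R1 + R2 -> LRCP`; complex internalization `LRCP -> LRCE`;
#' constitutive receptor cycling `R1 <-> R1E`, `R2 <-> R2E`; first-order
#' degradation of both complexes and of endosomal receptors; constitutive
#' receptor production. The deterministic mode uses an adaptive embedded
#' Cash-Karp Runge-Kutta 4(5) scheme with relative tolerance `ode_rtol`.
#'
#' The stochastic mode maps concentrations to molecule counts through
#' `volume`, advances with tau-leaping on a fixed grid of 1000 leaps per
#' iteration, and maps back; it uses R's RNG stream.
#'
#' @param state Named vector from [subcellular_state()], or a matrix with one
#'   row per cell and the seven species as columns.
#' @param params A [trafficking_params()].
#' @param dt_min Duration in minutes (default 30).
#' @param config A [sim_config()] (integration tolerances).
#' @param mode `"deterministic"` (default) or `"stochastic"`.
#' @param volume Count scaling for stochastic mode (molecules per mmol/l).
#' @return Same shape as `state`, advanced by `dt_min`.
#' @export
#' @examples
#' p <- trafficking_params()
#' trafficking_step(wound_start_state(), p)
trafficking_step <- function(state, params = trafficking_params(),
                             dt_min = 30, config = sim_config(),
                             mode = c("deterministic", "stochastic"),
                             volume = 1000) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "trafficking_params"))
  single <- is.null(dim(state))
  mat <- if (single) matrix(state, nrow = 1) else as.matrix(state)
  if (ncol(mat) != 7L) stop("trafficking_step(): state needs 7 species")
  if (any(mat < 0)) stop("trafficking_step(): concentrations must be >= 0")
  pv <- as.numeric(unlist(params))
  out <- if (mode == "deterministic") {
    trafficking_cpp(mat, pv, dt_min, config$ode_rtol, config$ode_atol)
  } else {
    tau_leap_step(mat, pv, dt_min, volume)
  }
  colnames(out) <- SPECIES
  if (single) setNames(drop(out), SPECIES) else out
}

# Tau-leaping over 1000 fixed leaps, vectorised across rows (cells/replicates).
# Concentration c maps to count round(c * volume); propensities use
# concentration-scale rates converted to count scale.
tau_leap_step <- function(mat, pv, dt_min, volume) {
  ka <- pv[1]; kic <- pv[2]; kir <- pv[3]; kr <- pv[4]
  kdc <- pv[5]; kdr <- pv[6]; p1 <- pv[7]; p2 <- pv[8]
  n_leap <- 1000L
  tau <- dt_min / n_leap
  cnt <- round(mat * volume)
  L <- cnt[, 1]; R1 <- cnt[, 2]; R2 <- cnt[, 3]; CP <- cnt[, 4]
  CE <- cnt[, 5]; E1 <- cnt[, 6]; E2 <- cnt[, 7]
  kaN <- ka / volume^2  # trimolecular rate on count scale
  for (s in seq_len(n_leap)) {
    f <- function(a) rpois(length(a), pmax(a, 0) * tau)
    nb <- f(kaN * L * R1 * R2)
    nb <- pmin(nb, L, R1, R2)          # cannot consume more than is present
    nic <- pmin(f(kic * CP), CP)
    ndc_p <- pmin(f(kdc * CP), pmax(CP - nic, 0))
    ndc_e <- pmin(f(kdc * CE), CE)
    nir1 <- pmin(f(kir * R1), pmax(R1 - nb, 0))
    nir2 <- pmin(f(kir * R2), pmax(R2 - nb, 0))
    nr1 <- pmin(f(kr * E1), E1)
    nr2 <- pmin(f(kr * E2), E2)
    ndr1 <- pmin(f(kdr * E1), pmax(E1 - nr1, 0))
    ndr2 <- pmin(f(kdr * E2), pmax(E2 - nr2, 0))
    np1 <- f(rep(p1 * volume, length(L)))
    np2 <- f(rep(p2 * volume, length(L)))
    L <- L - nb
    R1 <- R1 - nb - nir1 + nr1 + np1
    R2 <- R2 - nb - nir2 + nr2 + np2
    CP <- CP + nb - nic - ndc_p
    CE <- CE + nic - ndc_e
    E1 <- E1 + nir1 - nr1 - ndr1
    E2 <- E2 + nir2 - nr2 - ndr2
  }
  out <- cbind(L, R1, R2, CP, CE, E1, E2) / volume
  colnames(out) <- SPECIES
  out
}

#' Bond strengths from endosomal signal
#'
#' The endosomal ligand-receptor complex (LRCE) drives integrin (IN) and
#' protease (PR) expression, `IN = PR = Pi * LRCE` with Pi = 0.5, which in
#' turn modulate the cell-cell and cell-substrate bond strengths:
#' `CCB = CCB0 / (1 + PR)` (proteases loosen the sheet) and
#' `CSB = CSB0 * (1 + IN) / (1 + PR)` (integrins strengthen substrate
#' anchorage against protease turnover). At LRCE = 0 the defaults CCB0 and
#' CSB0 are recovered exactly; CCB is strictly decreasing in LRCE and CSB is
#' positive and bounded.
#'
#' @param LRCE Endosomal complex concentration, mmol/l (>= 0), vectorised.
#' @param config A [sim_config()] (supplies `Pi`, `ccb0`, `csb0`).
#' @return A data.frame with columns `IN`, `PR`, `CCB`, `CSB`.
#' @export
#' @examples
#' bond_strengths(c(0, 20))
bond_strengths <- function(LRCE, config = sim_config()) {
  if (any(LRCE < 0)) stop("bond_strengths(): LRCE must be >= 0")
  IN <- config$Pi * LRCE
  PR <- config$Pi * LRCE
  data.frame(IN = IN, PR = PR,
             CCB = config$ccb0 / (1 + PR),
             CSB = config$csb0 * (1 + IN) / (1 + PR))
}
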