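DIVISION_SCENARIOS <- c("on_pm_or_wound", "normal_uninhibited",
                        "stratified_ta_in_wound", "contact_inhibited_ta",
                        "contact_inhibited_stem")

# division probability for a scenario from the config DP table
division_probability <- function(scenario, config) {
  dp <- c(on_pm_or_wound = config$dp_on_pm_or_wound,
          normal_uninhibited = config$dp_normal,
          stratified_ta_in_wound = config$dp_stratified_ta_wound,
          contact_inhibited_ta = config$dp_contact_ta,
          contact_inhibited_stem = config$dp_contact_stem)
  unname(dp[scenario])
}

#' Decide a gated division attempt
#'
#' Draws a division decision for a proliferative (stem or TA) cell whose
#' cell-cycle clock has matured. The acceptance probability is the
#' scenario-specific division probability DP (90% on provisional matrix or in
#' the wound bed, 40% uninhibited in normal epidermis, 5% for stratified TA
#' in the wound bed, 2%/1% for contact-inhibited TA/stem) attenuated by the
#' endosomal TGF-beta1 signal:
#' \deqn{PRR = DP(scenario) / (1 + \lambda \cdot LRCE)}
#' which equals DP at LRCE = 0 and decreases monotonically in LRCE
#' (TGF-beta1 is a strong inhibitor of keratinocyte proliferation).
#'
#' @param subtype Cell subtype code or name; must be `stem` (0) or `TA` (1).
#' @param scenario One of
#'   `"on_pm_or_wound"`, `"normal_uninhibited"`, `"stratified_ta_in_wound"`,
#'   `"contact_inhibited_ta"`, `"contact_inhibited_stem"`.
#' @param LRCE Endosomal ligand-receptor complex, mmol/l (>= 0).
#' @param config A [sim_config()].
#' @param n Number of independent decisions to draw.
#' @return Logical vector of length `n`: divide or not.
#' @export
#' @examples
#' set.seed(1)
#' mean(division_decision("stem", "on_pm_or_wound", 0, n = 1e4))  # ~0.90
division_decision <- function(subtype, scenario, LRCE,
                              config = sim_config(), n = 1L) {
  if (is.character(subtype)) subtype <- SUBTYPE_LEVELS[[subtype]]
  if (!subtype %in% c(SUBTYPE_LEVELS[["stem"]], SUBTYPE_LEVELS[["TA"]])) {
    stop("division_decision(): only stem and TA cells may attempt division")
  }
  scenario <- match.arg(scenario, DIVISION_SCENARIOS)
  if (LRCE < 0) stop("division_decision(): LRCE must be >= 0")
  prr <- division_probability(scenario, config) /
    (1 + config$lambda_inhib * LRCE)
  runif(n) < prr
}

#' Classify the division scenario of a cell
#'
#' Maps a cell's surroundings onto the division-probability table:
#' \itemize{
#'   \item `on_pm_or_wound` -- the cell touches a provisional-matrix tile, or
#'     it is an unstratified cell in the wound bed;
#'   \item `stratified_ta_in_wound` -- a TA cell stratified (D >= 10 um) over
#'     the wound bed;
#'   \item `contact_inhibited_*` -- at least `contact_inhibit_neighbors`
#'     (10) neighbours within `contact_radius` (12 um) centre distance, or
#'     sustained mechanical compression (`pressure_inhibited`: residual pair
#'     overlap at least `overlap_inhibit` for `overlap_persist_h` straight
#'     -- crowding-induced cell-cycle arrest);
#'   \item `normal_uninhibited` otherwise.
#' }
#' The wound bed is anywhere over a tile that has not been remodeled back to
#' basement membrane (ECM_value >= 0.1).
#'
#' @param subtype Subtype code or name (`stem`/`TA`).
#' @param on_pm Logical; cell in contact with a provisional-matrix tile.
#' @param in_wound Logical; cell over a wound-bed (non-BM) tile.
#' @param D Stratification distance, um.
#' @param n_neighbors Number of neighbouring cells within `contact_radius`.
#' @param pressure_inhibited Logical; sustained-compression arrest signal.
#' @param config A [sim_config()].
#' @return Scenario name (character), vectorised over the inputs.
#' @export
classify_scenario <- function(subtype, on_pm, in_wound, D, n_neighbors,
                              pressure_inhibited = FALSE,
                              config = sim_config()) {
  if (is.character(subtype)) subtype <- SUBTYPE_LEVELS[subtype]
  n <- max(length(subtype), length(on_pm), length(in_wound), length(D),
           length(n_neighbors))
  subtype <- rep_len(subtype, n); on_pm <- rep_len(on_pm, n)
  in_wound <- rep_len(in_wound, n); D <- rep_len(D, n)
  n_neighbors <- rep_len(n_neighbors, n)
  pressure_inhibited <- rep_len(pressure_inhibited, n)
  stratified <- D >= config$strat_threshold
  out <- rep("normal_uninhibited", n)
  crowded <- n_neighbors >= config$contact_inhibit_neighbors |
    pressure_inhibited
  out[crowded & subtype == SUBTYPE_LEVELS[["TA"]]] <- "contact_inhibited_ta"
  out[crowded & subtype == SUBTYPE_LEVELS[["stem"]]] <- "contact_inhibited_stem"
  out[in_wound & stratified & subtype == SUBTYPE_LEVELS[["TA"]]] <-
    "stratified_ta_in_wound"
  out[on_pm | (in_wound & !stratified)] <- "on_pm_or_wound"
  out
}

#' One differentiation update for a cell
#'
#' The forward-only cascade stem -> TA -> committed -> corneocyte ->
#' (removed):
#' \itemize{
#'   \item stem -> TA when the stem cell has been stratified continuously for
#'     `strat_persist_h` (its stratification timer `strat_time_h` accumulates
#'     while D >= 10 um and resets below -- a transient mechanical bump does
#'     not trigger detachment-induced differentiation), or when it sits on
#'     the edge of a stem colony (< `colony_edge_neighbors` stem neighbours
#'     within `contact_radius`) whose connected size has reached
#'     `colony_size_threshold`;
#'   \item TA -> committed once stratification has persisted the same way
#'     (commitment is a suprabasal event) and the distance to the nearest
#'     stem cell reaches `ta_distance_threshold`;
#'   \item committed -> corneocyte after `committed_dwell_h` in the committed
#'     state, halved while touching a corneocyte (the ceramide/FAS-L
#'     differentiation signal passes only between committed cells and
#'     corneocytes);
#'   \item corneocytes desquamate (are removed) `corneocyte_dwell_h` after
#'     forming, closing the homeostatic loop.
#' }
#'
#' @param subtype Subtype code or name.
#' @param strat_time_h Hours of uninterrupted stratification (D >= 10 um).
#' @param n_stem_neighbors Stem neighbours within `contact_radius`.
#' @param colony_size Size of the cell's connected stem colony (stems only).
#' @param dist_nearest_stem Distance to the nearest stem cell, um (`Inf` if
#'   no stem cells exist).
#' @param stage_time_h Hours spent in the current subtype.
#' @param touching_corneocyte Logical; in contact with a corneocyte.
#' @param config A [sim_config()].
#' @return New subtype code, vectorised; `NA` marks a desquamated corneocyte
#'   (to be removed from the world).
#' @export
differentiation_step <- function(subtype, strat_time_h, n_stem_neighbors,
                                 colony_size, dist_nearest_stem, stage_time_h,
                                 touching_corneocyte,
                                 config = sim_config()) {
  if (is.character(subtype)) subtype <- SUBTYPE_LEVELS[subtype]
  n <- length(subtype)
  out <- as.integer(subtype)
  stem <- SUBTYPE_LEVELS[["stem"]]; ta <- SUBTYPE_LEVELS[["TA"]]
  com <- SUBTYPE_LEVELS[["committed"]]; cor <- SUBTYPE_LEVELS[["corneocyte"]]
  stratified <- strat_time_h >= config$strat_persist_h

  is_stem <- subtype == stem
  promote_stem <- is_stem &
    (stratified |
       (colony_size >= config$colony_size_threshold &
          n_stem_neighbors < config$colony_edge_neighbors))
  out[promote_stem] <- ta

  is_ta <- subtype == ta
  out[is_ta & stratified &
        dist_nearest_stem >= config$ta_distance_threshold] <- com

  is_com <- subtype == com
  dwell <- ifelse(touching_corneocyte, config$committed_dwell_h / 2,
                  config$committed_dwell_h)
  out[is_com & stage_time_h >= dwell] <- cor

  is_cor <- subtype == cor
  out[is_cor & stage_time_h >= config$corneocyte_dwell_h] <- NA_integer_
  out
}

#' Active migration displacement of a TA cell
#'
#' Only TA cells move actively, at 1 um/min (30 um per iteration), and only
#' while they keep contact with the cell sheet. With probability `p_bias`
#' (0.8) the step points horizontally toward the nearest provisional-matrix
#' tile within the 60-um sensing radius (if there is one); otherwise the
#' direction is uniform random horizontal. Two conditions cancel a move
#' (zero displacement): a cell with no neighbour within bond range has lost
#' contact with the sheet and does not migrate, and a destination already
#' occupied -- any other cell centre within one cell diameter of the target
#' -- blocks the move (contact inhibition of locomotion; cells crawl into
#' free territory such as a denuded wound bed, not through intact tissue).
#'
#' @param subtype Subtype code or name of the moving cell.
#' @param pos Length-3 position of the cell, um.
#' @param neighbor_pos Matrix (n x 3) of the other cells' positions, um.
#' @param pm_tile_centers Matrix (m x 2) of provisional-matrix tile centres
#'   (may have zero rows).
#' @param config A [sim_config()].
#' @return Length-3 displacement vector in um (zero for non-TA, isolated, or
#'   cancelled moves).
#' @export
migration_step <- function(subtype, pos, neighbor_pos,
                           pm_tile_centers = matrix(numeric(0), ncol = 2),
                           config = sim_config()) {
  if (is.character(subtype)) subtype <- SUBTYPE_LEVELS[[subtype]]
  if (subtype != SUBTYPE_LEVELS[["TA"]]) return(c(0, 0, 0))
  # contact gate: only cells attached to the sheet migrate actively
  if (nrow(neighbor_pos) == 0) return(c(0, 0, 0))
  d_before <- sqrt(colSums((t(neighbor_pos) - pos)^2))
  if (min(d_before) > 2 * CELL_RADIUS + config$bond_range) return(c(0, 0, 0))
  step_len <- config$migration_speed * config$dt_min

  dir2 <- NULL
  if (nrow(pm_tile_centers) > 0) {
    dx <- pm_tile_centers[, 1] - pos[1]
    dy <- pm_tile_centers[, 2] - pos[2]
    d <- sqrt(dx^2 + dy^2)
    k <- which.min(d)
    if (d[k] <= config$sensing_radius && runif(1) < config$p_bias) {
      dir2 <- if (d[k] < 1e-12) NULL else c(dx[k], dy[k]) / d[k]
    }
  }
  if (is.null(dir2)) {
    theta <- runif(1, 0, 2 * pi)
    dir2 <- c(cos(theta), sin(theta))
  }
  disp <- c(dir2 * step_len, 0)
  # contact inhibition of locomotion: an occupied destination blocks the move
  target <- pos + disp
  d_target <- sqrt(colSums((t(neighbor_pos) - target)^2))
  if (min(d_target) < 2 * CELL_RADIUS) return(c(0, 0, 0))
  disp
}
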