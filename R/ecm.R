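#' Deposit newly synthesized latent TGF-beta1
#'
#' A cell's freshly translated latent TGF-beta1 is split between the matrix
#' tile underneath it and the membranes of neighbouring cells -- there is no
#' free diffusion. The tile receives the class-dependent fraction alpha
#' (0.90 on provisional matrix, 0.01 on secondary matrix and basement
#' membrane), appended to its latent store as a parcel stamped with the
#' current iteration. The remainder is split equally as active membrane
#' credits among the neighbours within bond range; with no neighbour the
#' remainder is discarded.
#'
#' @param produced Amount synthesized this iteration (mmol/l-equivalent, >= 0).
#' @param tile A list with `ecm_value` and `store` (a parcel data.frame).
#' @param neighbor_ids Identifiers of cells within bond range (may be empty).
#' @param iteration Current iteration counter.
#' @param config A [sim_config()].
#' @return A list: `tile` (updated), `membrane_credits` (named numeric vector
#'   over `neighbor_ids`), `deposited`, `discarded`.
#' @export
#' @examples
#' tile <- list(ecm_value = 1, store = new_parcels())
#' deposit_latent(100, tile, neighbor_ids = c(7, 9), iteration = 0)
deposit_latent <- function(produced, tile, neighbor_ids = integer(0),
                           iteration = 0L, config = sim_config()) {
  if (produced < 0) stop("deposit_latent(): produced must be >= 0")
  alpha <- deposition_fraction(tile$ecm_value, config)
  deposited <- alpha * produced
  remainder <- produced - deposited
  if (deposited > 0) {
    tile$store <- add_parcel(tile$store, deposited, iteration)
  }
  if (length(neighbor_ids) && remainder > 0) {
    credits <- setNames(rep(remainder / length(neighbor_ids),
                            length(neighbor_ids)),
                        as.character(neighbor_ids))
    discarded <- 0
  } else {
    credits <- setNames(numeric(0), character(0))
    discarded <- remainder
  }
  list(tile = tile, membrane_credits = credits,
       deposited = deposited, discarded = discarded)
}

# alpha by tile class (PM / SM / BM bands of ECM_value)
deposition_fraction <- function(ecm_value, config) {
  cls <- tile_class(ecm_value)
  ifelse(cls == TILE_CLASS_CODES[["PM"]], config$alpha_pm,
         ifelse(cls == TILE_CLASS_CODES[["SM"]], config$alpha_sm,
                config$alpha_bm))
}

#' Contact activation of stored latent TGF-beta1
#'
#' Latent TGF-beta1 in a tile store is activated only by cells in direct
#' contact with the tile. Each contacting cell retrieves an equal share of
#' the whole store; of each retrieval, the fraction kappa (0.90) appears as
#' active ligand on that cell's membrane and the remainder is destroyed in
#' the activation step. Without contact the store is untouched.
#'
#' @param tile A list with `ecm_value` and `store` (parcel data.frame).
#' @param contacting_ids Identifiers of cells in contact (may be empty).
#' @param config A [sim_config()].
#' @return A list: `tile` (store emptied if any contact), `active_gained`
#'   (named vector over `contacting_ids`), `retrieved`, `activation_loss`.
#' @export
#' @examples
#' tile <- list(ecm_value = 1, store = add_parcel(new_parcels(), 100, 0))
#' activate_latent(tile, contacting_ids = 42)
activate_latent <- function(tile, contacting_ids = integer(0),
                            config = sim_config()) {
  n <- length(contacting_ids)
  total <- parcel_total(tile$store)
  if (n == 0 || total == 0) {
    return(list(tile = tile,
                active_gained = setNames(numeric(0), character(0)),
                retrieved = 0, activation_loss = 0))
  }
  share <- total / n
  gained <- setNames(rep(config$kappa * share, n), as.character(contacting_ids))
  tile$store <- new_parcels()
  list(tile = tile, active_gained = gained, retrieved = total,
       activation_loss = (1 - config$kappa) * total)
}

#' Remodel a tile under keratinocyte contact
#'
#' Cell contact drives the matrix along the provisional -> secondary ->
#' basement-membrane axis: `ECM_value` drops by `remodel_rate` (0.01 by
#' default) per contacting cell per iteration, floored at 0. Class
#' transitions emerge from the [tile_weights()] bands. No contact, no
#' remodeling; `ECM_value` never increases except at wound events.
#'
#' @param ecm_value Current ECM_value in [0, 1], vectorised.
#' @param n_contacting Number of contacting keratinocytes (>= 0), vectorised.
#' @param config A [sim_config()].
#' @return Updated ECM_value vector.
#' @export
#' @examples
#' remodel_tile(1.0, 1)    # 0.99
#' remodel_tile(0.005, 10) # clamped at 0
remodel_tile <- function(ecm_value, n_contacting, config = sim_config()) {
  if (any(n_contacting < 0)) stop("remodel_tile(): n_contacting must be >= 0")
  pmax(0, ecm_value - config$remodel_rate * n_contacting)
}
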