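#' Timestamped TGF-beta1 parcel stores
#'
#' Latent TGF-beta1 in a tile and active TGF-beta1 on a cell membrane are both
#' kept as parcels: (amount, deposit_iteration) pairs. A parcel is removed
#' exactly when its age reaches the configured lifetime (48 h = 96 iterations
#' by default) -- a sharp cutoff, not an exponential decay, because the
#' lifetime is specified as a span within which the molecule degrades.
#'
#' `new_parcels()` builds an empty store; `add_parcel()` appends;
#' `parcel_total()` sums the amounts.
#'
#' @param amount,deposit_iteration Parcel fields.
#' @param parcels A parcel data.frame.
#' @return `new_parcels`/`add_parcel`: a parcel data.frame;
#'   `parcel_total`: a number.
#' @export
new_parcels <- function() {
  data.frame(amount = numeric(0), deposit_iteration = integer(0))
}

#' @rdname new_parcels
#' @export
add_parcel <- function(parcels, amount, deposit_iteration) {
  stopifnot(amount >= 0)
  if (amount == 0) return(parcels)
  rbind(parcels, data.frame(amount = amount,
                            deposit_iteration = as.integer(deposit_iteration)))
}

#' @rdname new_parcels
#' @export
parcel_total <- function(parcels) sum(parcels$amount)

#' Age a parcel store and remove expired parcels
#'
#' Removes every parcel whose age, in iterations, has reached the TGF-beta1
#' lifetime (`tgfb_lifetime_h`, 48 h by default, i.e. 96 30-minute
#' iterations). A parcel deposited at iteration t is present through iteration
#' t + 95 and gone at t + 96. Applies identically to tile latent stores and
#' cell membrane stores.
#'
#' @param parcels A parcel data.frame (see [new_parcels()]).
#' @param iteration Current iteration counter.
#' @param config A [sim_config()].
#' @return The surviving parcels.
#' @export
#' @examples
#' p <- add_parcel(new_parcels(), 10, 0)
#' nrow(age_and_degrade(p, 95))  # 1: still present
#' nrow(age_and_degrade(p, 96))  # 0: expired at 48 h
age_and_degrade <- function(parcels, iteration, config = sim_config()) {
  if (any(parcels$amount < 0)) stop("age_and_degrade(): negative parcel amount")
  keep <- (iteration - parcels$deposit_iteration) < lifetime_iterations(config)
  parcels[keep, , drop = FALSE]
}

# ---- ring-buffer parcel stores (engine internals) -------------------------
#
# The engine keeps parcel stores for all agents of a kind as one matrix with
# one row per agent and `lifetime_iterations` columns: column (t mod L) + 1
# holds the amount deposited at iteration t. Advancing to iteration t first
# zeroes that column (whatever sat there was deposited at t - L and has just
# reached the lifetime), which reproduces the sharp-cutoff rule of
# age_and_degrade() exactly; an equivalence test pins the two together.

ring_new <- function(n_agents, config) {
  matrix(0, nrow = n_agents, ncol = lifetime_iterations(config))
}

ring_col <- function(iteration, config) {
  (iteration %% lifetime_iterations(config)) + 1L
}

# expire parcels deposited `lifetime` iterations ago; returns list(ring, expired)
ring_age <- function(ring, iteration, config) {
  col <- ring_col(iteration, config)
  expired <- sum(ring[, col])
  ring[, col] <- 0
  list(ring = ring, expired = expired)
}

ring_add <- function(ring, rows, amounts, iteration, config) {
  col <- ring_col(iteration, config)
  if (length(rows)) {
    agg <- tapply(amounts, rows, sum)
    idx <- as.integer(names(agg))
    ring[idx, col] <- ring[idx, col] + as.numeric(agg)
  }
  ring
}

ring_total <- function(ring) {
  if (nrow(ring) == 0) numeric(0) else rowSums(ring)
}

# scale each row to a new total (used after the ODE consumes membrane ligand)
ring_rescale <- function(ring, new_total) {
  old <- ring_total(ring)
  f <- ifelse(old > 0, new_total / old, 0)
  ring * f
}

# convert one ring row to the public parcel data.frame (ages unknown beyond
# the bin structure: bins map back to the most recent deposit iterations)
ring_to_parcels <- function(ring, row, iteration, config) {
  L <- lifetime_iterations(config)
  out <- new_parcels()
  for (age in 0:(L - 1)) {
    t0 <- iteration - age
    if (t0 < 0) break
    col <- ring_col(t0, config)
    amt <- ring[row, col]
    if (amt > 0) out <- add_parcel(out, amt, t0)
  }
  out
}
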