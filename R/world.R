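#' Seed a virtual basement membrane with stem cells
#'
#' Builds a world: an Lx x Ly um basement-membrane surface exactly tiled by
#' 20-um ECM tiles (all ECM_value = 0), a 100-um wall around it, and `n_stem`
#' keratinocyte stem cells resting on the substrate at uniformly random,
#' non-overlapping positions. Subcellular species start at the
#' normal-condition concentrations (see [subcellular_state()]). The same seed
#' always reproduces the same world.
#'
#' @param n_stem Number of stem cells to seed (default from `config`).
#' @param lx,ly Surface dimensions in um; positive multiples of the tile side.
#' @param seed Integer RNG seed.
#' @param config A [sim_config()].
#' @return An object of class `epi_world`.
#' @export
#' @examples
#' w <- seed_world(30, 100, 100, seed = 1)
#' census(w)$total_agents  # 30 cells + 25 tiles + 1 solver agent
seed_world <- function(n_stem = config$n_seed_stem, lx = config$lx,
                       ly = config$ly, seed = 1L, config = sim_config()) {
  if (n_stem < 0 || n_stem != round(n_stem)) {
    stop("seed_world(): n_stem must be a non-negative integer")
  }
  side <- config$tile_side
  if (lx <= 0 || ly <= 0 ||
      abs(lx / side - round(lx / side)) > 1e-9 ||
      abs(ly / side - round(ly / side)) > 1e-9) {
    stop("seed_world(): lx and ly must be positive multiples of ", side, " um")
  }
  set.seed(seed)

  nx <- as.integer(round(lx / side)); ny <- as.integer(round(ly / side))
  grid <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  tiles <- data.frame(
    id = seq_len(nrow(grid)),
    i = grid$i, j = grid$j,
    cx = (grid$i + 0.5) * side, cy = (grid$j + 0.5) * side,
    ecm_value = 0
  )

  pos <- sample_nonoverlapping(n_stem, lx, ly)
  cells <- new_cells_df(n_stem)
  if (n_stem > 0) {
    cells$id <- seq_len(n_stem)
    cells$x <- pos[, 1]; cells$y <- pos[, 2]; cells$z <- CELL_RADIUS
  }

  world <- structure(list(
    cells = cells,
    cell_store = ring_new(n_stem, config),
    tiles = tiles,
    tile_store = ring_new(nrow(tiles), config),
    iteration = 0L,
    dims = c(lx = lx, ly = ly),
    wall_height = config$wall_height,
    config = config,
    next_id = n_stem + 1L,
    division_log = data.frame(iteration = integer(0), z = numeric(0)),
    rng_state = NULL
  ), class = "epi_world")
  if (n_stem > 0) {
    world$cell_store <- ring_add(world$cell_store, seq_len(n_stem),
                                 cells$ligand, 0L, config)
  }
  world$rng_state <- .Random.seed
  world
}

# empty cell table with normal-condition subcellular state
new_cells_df <- function(n) {
  sub <- subcellular_state()
  df <- data.frame(
    id = integer(n), subtype = rep(SUBTYPE_LEVELS[["stem"]], n),
    x = numeric(n), y = numeric(n), z = numeric(n),
    age_h = numeric(n), cycle_clock_h = numeric(n), stage_time_h = numeric(n),
    strat_time_h = numeric(n), press_time_h = numeric(n),
    ligand = rep(sub[["ligand"]], n),
    R1 = rep(sub[["R1"]], n), R2 = rep(sub[["R2"]], n),
    LRCP = rep(sub[["LRCP"]], n), LRCE = rep(sub[["LRCE"]], n),
    R1E = rep(sub[["R1E"]], n), R2E = rep(sub[["R2E"]], n),
    PRO = numeric(n), mRNA = numeric(n)
  )
  b <- bond_strengths(df$LRCE, sim_config())
  df$IN <- b$IN; df$PR <- b$PR; df$CCB <- b$CCB; df$CSB <- b$CSB
  df
}

# rejection-sample n non-overlapping resting positions on the surface
sample_nonoverlapping <- function(n, lx, ly, max_attempts = 10000L) {
  pos <- matrix(numeric(0), ncol = 2)
  attempts <- 0L
  while (nrow(pos) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("seed_world(): packing failure -- could not place ", n,
           " non-overlapping cells on a ", lx, " x ", ly,
           " um surface after ", max_attempts, " attempts")
    }
    cand <- c(runif(1, CELL_RADIUS, lx - CELL_RADIUS),
              runif(1, CELL_RADIUS, ly - CELL_RADIUS))
    if (nrow(pos) == 0 ||
        min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >=
          2 * CELL_RADIUS) {
      pos <- rbind(pos, cand)
    }
  }
  pos
}

#' Scratch-wound a world
#'
#' Removes every cell whose centre lies inside the axis-aligned box, resets
#' the tiles under the box footprint (when the box reaches the substrate) to
#' provisional matrix (ECM_value = 1) with their latent stores cleared, and
#' puts cells within one cell diameter (10 um) of the box boundary into the
#' wound-onset subcellular state (LRCP = 20, LRCE = 20, active membrane
#' ligand 100 mmol/l; receptors unchanged), representing the burst of active
#' TGF-beta1 released by platelets and macrophages at the injury site. An
#' empty box is a no-op.
#'
#' @param world An `epi_world`.
#' @param box Numeric vector `c(x0, y0, z0, x1, y1, z1)` in um.
#' @return The wounded world.
#' @export
wound_world <- function(world, box) {
  stopifnot(inherits(world, "epi_world"), is.numeric(box), length(box) == 6)
  lo <- box[1:3]; hi <- box[4:6]
  if (any(hi < lo)) stop("wound_world(): box must satisfy x0<=x1, y0<=y1, z0<=z1")
  cfg <- world$config
  cells <- world$cells

  inside <- cells$x >= lo[1] & cells$x <= hi[1] &
    cells$y >= lo[2] & cells$y <= hi[2] &
    cells$z >= lo[3] & cells$z <= hi[3]

  # margin: surviving cells within one cell diameter of the box
  dx <- pmax(lo[1] - cells$x, 0, cells$x - hi[1])
  dy <- pmax(lo[2] - cells$y, 0, cells$y - hi[2])
  dz <- pmax(lo[3] - cells$z, 0, cells$z - hi[3])
  near <- !inside & sqrt(dx^2 + dy^2 + dz^2) <= 2 * CELL_RADIUS

  ws <- wound_start_state()
  if (any(near)) {
    cells$LRCP[near] <- ws[["LRCP"]]
    cells$LRCE[near] <- ws[["LRCE"]]
    cells$ligand[near] <- ws[["ligand"]]
    idx <- which(near)
    world$cell_store[idx, ] <- 0
    world$cell_store <- ring_add(world$cell_store, idx,
                                 rep(ws[["ligand"]], length(idx)),
                                 world$iteration, cfg)
  }

  world$cells <- cells[!inside, , drop = FALSE]
  world$cell_store <- world$cell_store[!inside, , drop = FALSE]

  # tiles under the footprint become provisional matrix if the box reaches z=0
  if (lo[3] <= 0 && hi[3] >= 0) {
    t_in <- world$tiles$cx >= lo[1] & world$tiles$cx <= hi[1] &
      world$tiles$cy >= lo[2] & world$tiles$cy <= hi[2]
    world$tiles$ecm_value[t_in] <- 1
    world$tile_store[t_in, ] <- 0
  }
  world
}

#' Summarise a world
#'
#' Counts cells per subtype and tiles per matrix class, reports the total
#' agent count (cells + tiles + the one physical-solver agent, matching the
#' source model's agent accounting), a 10-um height histogram per subtype,
#' and the fraction of recent division events that occurred within 20 um of
#' the substrate.
#'
#' @param world An `epi_world`.
#' @return A list with elements `n_cells`, `n_tiles`, `total_agents`,
#'   `subtype_counts`, `tile_counts`, `height_hist`,
#'   `basal_division_fraction`.
#' @export
census <- function(world) {
  stopifnot(inherits(world, "epi_world"))
  cells <- world$cells
  subtype_counts <- vapply(SUBTYPE_LEVELS, function(code) {
    sum(cells$subtype == code)
  }, integer(1))
  cls <- tile_class(world$tiles$ecm_value)
  tile_counts <- vapply(TILE_CLASS_CODES, function(code) sum(cls == code),
                        integer(1))
  breaks <- seq(0, max(world$wall_height, 10), by = 10)
  if (max(breaks) < world$wall_height) breaks <- c(breaks, world$wall_height)
  hist_m <- sapply(SUBTYPE_LEVELS, function(code) {
    zs <- cells$z[cells$subtype == code]
    as.integer(table(cut(pmin(zs, max(breaks) - 1e-9), breaks,
                         right = FALSE)))
  })
  if (is.null(dim(hist_m))) hist_m <- matrix(hist_m, ncol = 4)
  colnames(hist_m) <- names(SUBTYPE_LEVELS)
  rownames(hist_m) <- paste0("[", head(breaks, -1), ",", breaks[-1], ")")
  dl <- world$division_log
  recent <- dl[dl$iteration > world$iteration - world$config$plateau_window, ,
               drop = FALSE]
  basal_frac <- if (nrow(recent)) mean(recent$z <= 20) else NA_real_
  list(
    n_cells = nrow(cells),
    n_tiles = nrow(world$tiles),
    total_agents = nrow(cells) + nrow(world$tiles) + 1L,
    subtype_counts = subtype_counts,
    tile_counts = tile_counts,
    height_hist = hist_m,
    basal_division_fraction = basal_frac
  )
}

#' @export
print.epi_world <- function(x, ...) {
  cs <- census(x)
  cat("<epi_world> iteration ", x$iteration, " (",
      x$iteration * x$config$dt_min / 60, " h)\n", sep = "")
  cat("  surface ", x$dims[["lx"]], " x ", x$dims[["ly"]], " um, ",
      cs$n_tiles, " tiles (BM ", cs$tile_counts[["BM"]], ", SM ",
      cs$tile_counts[["SM"]], ", PM ", cs$tile_counts[["PM"]], ")\n", sep = "")
  cat("  cells ", cs$n_cells, ": ",
      paste(names(cs$subtype_counts), cs$subtype_counts, collapse = ", "),
      "\n", sep = "")
  cat("  total agents (incl. solver): ", cs$total_agents, "\n", sep = "")
  invisible(x)
}

# index of the tile under a cell's (x, y); NA outside the surface
tile_under <- function(world, x, y) {
  side <- world$config$tile_side
  nx <- as.integer(round(world$dims[["lx"]] / side))
  ny <- as.integer(round(world$dims[["ly"]] / side))
  i <- pmin(pmax(floor(x / side), 0), nx - 1)
  j <- pmin(pmax(floor(y / side), 0), ny - 1)
  as.integer(j * nx + i + 1L)
}
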