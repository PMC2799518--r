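#' Advance the world by one 30-minute iteration
#'
#' Executes the phases of one model iteration in a fixed order:
#' \enumerate{
#'   \item build neighbour and tile-contact indices (the message-board
#'     surrogate);
#'   \item ECM and subcellular phase: age latent and membrane TGF-beta1
#'     stores, remodel tiles under contact, then per cell: matrix-class
#'     weights, promoter activity, capped transcription/translation,
#'     deposition of the new latent TGF-beta1 (tile share plus neighbour
#'     membrane credits), contact activation of tile stores, the trafficking
#'     network step, and bond-strength update from the endosomal signal;
#'   \item biology phase: gated division decisions, the differentiation
#'     cascade (including corneocyte desquamation), and active TA migration;
#'   \item mechanics resolve;
#' }
#' then increments the iteration counter (+30 simulated minutes). Division
#' and migration use the subcellular state computed earlier in the same
#' iteration. The world carries its own RNG stream so replays with the same
#' seed are identical.
#'
#' Diagnostics from the step are attached to the returned world:
#' `last_ledger` (the TGF-beta1 mass ledger of the iteration), `last_events`
#' (division/differentiation/desquamation records) and `last_resolve`
#' (mechanics convergence).
#'
#' @param world An `epi_world`.
#' @param config Configuration; defaults to the world's own.
#' @param quiet Suppress the mechanics non-convergence warning.
#' @return The advanced world.
#' @export
step_world <- function(world, config = world$config, quiet = FALSE) {
  stopifnot(inherits(world, "epi_world"))
  cfg <- config
  if (!is.null(world$rng_state)) {
    assign(".Random.seed", world$rng_state, envir = globalenv())
  }
  it <- world$iteration
  cells <- world$cells
  n <- nrow(cells)
  dt_h <- cfg$dt_min / 60
  lifetime <- lifetime_iterations(cfg)
  bond_reach <- 2 * CELL_RADIUS + cfg$bond_range

  ledger <- list(produced = 0, deposited = 0, credited = 0, discarded = 0,
                 retrieved = 0, activated = 0, activation_loss = 0,
                 expired_tile = 0, expired_membrane = 0)
  events <- list()

  ## ---- (1) indices ----
  pairs <- neighbor_pairs_cpp(cells$x, cells$y, cells$z, bond_reach)
  pi_ <- pairs[, 1]; pj <- pairs[, 2]; pd <- pairs[, 3]
  deg_bond <- tabulate(c(pi_, pj), nbins = n)
  close_pair <- pd <= cfg$contact_radius
  deg_close <- tabulate(c(pi_[close_pair], pj[close_pair]), nbins = n)
  tile_idx <- tile_under(world, cells$x, cells$y)
  contact <- cells$z - CELL_RADIUS <= cfg$bond_range  # bottom within 5 um
  living <- cells$subtype < SUBTYPE_LEVELS[["corneocyte"]]

  ## ---- (2) ECM + subcellular phase ----
  if (it >= lifetime) {  # nothing can be old enough before one lifetime
    ta <- ring_age(world$tile_store, it, cfg)
    world$tile_store <- ta$ring; ledger$expired_tile <- ta$expired
    ca <- ring_age(world$cell_store, it, cfg)
    world$cell_store <- ca$ring; ledger$expired_membrane <- ca$expired
  }

  n_contact_tile <- tabulate(tile_idx[contact & living],
                             nbins = nrow(world$tiles))
  world$tiles$ecm_value <- remodel_tile(world$tiles$ecm_value, n_contact_tile,
                                        cfg)

  if (n > 0) {
    ecm_under <- world$tiles$ecm_value[tile_idx]
    w <- tile_weights(ecm_under)
    PRO <- promoter_activity(w, contact, cells$LRCP, cells$z, cfg)
    PRO[cells$subtype > SUBTYPE_LEVELS[["TA"]]] <- 0  # only stem/TA express
    tt <- transcribe_translate(PRO, cfg)
    cells$PRO <- PRO; cells$mRNA <- tt$mRNA
    produced <- tt$latent
    ledger$produced <- sum(produced)

    # deposition: alpha share into the tile underneath ...
    alpha <- deposition_fraction(ecm_under, cfg)
    dep <- alpha * produced
    world$tile_store <- ring_add(world$tile_store, tile_idx, dep, it, cfg)
    ledger$deposited <- sum(dep)
    # ... remainder split equally over bond-range neighbours' membranes
    remainder <- produced - dep
    credits <- numeric(n)
    if (nrow(pairs)) {
      give <- ifelse(deg_bond > 0, remainder / pmax(deg_bond, 1), 0)
      contrib <- c(give[pj], give[pi_])
      recv <- c(pi_, pj)
      agg <- rowsum(contrib, recv)
      credits[as.integer(rownames(agg))] <- agg[, 1]
    }
    ledger$credited <- sum(credits)
    ledger$discarded <- sum(remainder[deg_bond == 0])

    # contact activation of tile stores (equal split, kappa to the membrane)
    store_tot <- ring_total(world$tile_store)
    act_gain <- numeric(n)
    contact_idx <- which(contact & living)
    if (length(contact_idx)) {
      per_tile_n <- tabulate(tile_idx[contact_idx], nbins = nrow(world$tiles))
      touched <- which(per_tile_n > 0 & store_tot > 0)
      if (length(touched)) {
        share <- store_tot[tile_idx[contact_idx]] /
          per_tile_n[tile_idx[contact_idx]]
        share[!(tile_idx[contact_idx] %in% touched)] <- 0
        act_gain[contact_idx] <- cfg$kappa * share
        retrieved <- sum(store_tot[touched])
        ledger$retrieved <- retrieved
        ledger$activated <- cfg$kappa * retrieved
        ledger$activation_loss <- (1 - cfg$kappa) * retrieved
        world$tile_store[touched, ] <- 0
      }
    }

    # new active ligand parcels on the membranes (fresh 48-h clock)
    gains <- credits + act_gain
    gidx <- which(gains > 0)
    world$cell_store <- ring_add(world$cell_store, gidx, gains[gidx], it, cfg)

    # trafficking network step for every cell
    lig <- ring_total(world$cell_store)
    state <- cbind(lig, cells$R1, cells$R2, cells$LRCP, cells$LRCE,
                   cells$R1E, cells$R2E)
    out <- trafficking_cpp(state, as.numeric(unlist(trafficking_params(cfg))),
                           cfg$dt_min, cfg$ode_rtol, cfg$ode_atol)
    world$cell_store <- ring_rescale(world$cell_store, out[, 1])
    cells$ligand <- out[, 1]
    cells$R1 <- out[, 2]; cells$R2 <- out[, 3]
    cells$LRCP <- out[, 4]; cells$LRCE <- out[, 5]
    cells$R1E <- out[, 6]; cells$R2E <- out[, 7]

    b <- bond_strengths(cells$LRCE, cfg)
    cells$IN <- b$IN; cells$PR <- b$PR; cells$CCB <- b$CCB; cells$CSB <- b$CSB
  }

  ## ---- (3) biology phase ----
  cells$age_h <- cells$age_h + dt_h
  cells$cycle_clock_h <- cells$cycle_clock_h + dt_h
  cells$stage_time_h <- cells$stage_time_h + dt_h
  # stratification persistence timer: runs while D >= threshold, else resets
  cells$strat_time_h <- ifelse(cells$z >= cfg$strat_threshold,
                               cells$strat_time_h + dt_h, 0)
  # compression persistence timer: residual (post-mechanics) overlap above
  # the arrest threshold accumulates; relaxed cells reset
  if (n > 0) {
    max_ov <- numeric(n)
    ov_pair <- pd < 2 * CELL_RADIUS
    if (any(ov_pair)) {
      ov <- 2 * CELL_RADIUS - pd[ov_pair]
      agg <- tapply(c(ov, ov), c(pi_[ov_pair], pj[ov_pair]), max)
      max_ov[as.integer(names(agg))] <- as.numeric(agg)
    }
    cells$press_time_h <- ifelse(max_ov >= cfg$overlap_inhibit,
                                 cells$press_time_h + dt_h, 0)
  }

  daughters <- NULL
  daughter_store <- NULL
  if (n > 0) {
    on_pm <- contact & tile_class(world$tiles$ecm_value[tile_idx]) ==
      TILE_CLASS_CODES[["PM"]]
    in_wound <- world$tiles$ecm_value[tile_idx] >= 0.1

    eligible <- which(cells$subtype <= SUBTYPE_LEVELS[["TA"]] &
                        cells$cycle_clock_h >= cfg$cycle_length_h)
    if (length(eligible)) {
      scen <- classify_scenario(cells$subtype[eligible], on_pm[eligible],
                                in_wound[eligible], cells$z[eligible],
                                deg_close[eligible],
                                cells$press_time_h[eligible] >=
                                  cfg$overlap_persist_h, cfg)
      prr <- division_probability(scen, cfg) /
        (1 + cfg$lambda_inhib * cells$LRCE[eligible])
      divide <- runif(length(eligible)) < prr
      cells$cycle_clock_h[eligible] <- 0  # the attempt consumes the cycle
      div_idx <- eligible[divide]
      if (length(div_idx)) {
        nd <- length(div_idx)
        u <- matrix(rnorm(3 * nd), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        # basal mitoses: near-planar placement while the sheet has room, but
        # steeply upward (delaminating daughter) once the neighbourhood is
        # crowded, so divisions do not shove other basal cells out of the
        # sheet
        basal <- contact[div_idx]
        if (any(basal)) {
          nb <- sum(basal)
          crowded <- deg_close[div_idx][basal] >= 6
          th <- runif(nb, 0, 2 * pi)
          pitch <- ifelse(crowded, runif(nb, 60, 85), runif(nb, 5, 25)) *
            pi / 180
          u[basal, 1] <- cos(th) * cos(pitch)
          u[basal, 2] <- sin(th) * cos(pitch)
          u[basal, 3] <- sin(pitch)
        }
        daughters <- cells[div_idx, , drop = FALSE]
        daughters$id <- seq(world$next_id, length.out = nd)
        world$next_id <- world$next_id + nd
        daughters$x <- cells$x[div_idx] + 2 * CELL_RADIUS * u[, 1]
        daughters$y <- cells$y[div_idx] + 2 * CELL_RADIUS * u[, 2]
        daughters$z <- pmax(cells$z[div_idx] + 2 * CELL_RADIUS * u[, 3], 0)
        daughters$age_h <- 0; daughters$cycle_clock_h <- 0
        daughters$stage_time_h <- 0; daughters$strat_time_h <- 0
        daughters$press_time_h <- 0
        # membrane ligand splits between the two daughters
        daughter_store <- world$cell_store[div_idx, , drop = FALSE] / 2
        world$cell_store[div_idx, ] <- world$cell_store[div_idx, ] / 2
        cells$ligand[div_idx] <- cells$ligand[div_idx] / 2
        daughters$ligand <- daughters$ligand / 2
        events$division <- data.frame(iteration = it, event = "division",
                                      cell_id = cells$id[div_idx],
                                      z = cells$z[div_idx])
        world$division_log <- rbind(world$division_log,
                                    data.frame(iteration = it,
                                               z = cells$z[div_idx]))
      }
    }

    # differentiation cascade (pre-division context, existing cells only)
    stem_mask <- cells$subtype == SUBTYPE_LEVELS[["stem"]]
    stem_pair <- close_pair & stem_mask[pi_] & stem_mask[pj]
    n_stem_nb <- tabulate(c(pi_[close_pair & stem_mask[pj]],
                            pj[close_pair & stem_mask[pi_]]), nbins = n)
    colony <- stem_colony_sizes(n, which(stem_mask),
                                cbind(pi_[stem_pair], pj[stem_pair]))
    dist_stem <- nearest_dist_cpp(cells$x, cells$y, cells$z,
                                  cells$x[stem_mask], cells$y[stem_mask],
                                  cells$z[stem_mask])
    dist_stem[stem_mask] <- 0
    cor_mask <- cells$subtype == SUBTYPE_LEVELS[["corneocyte"]]
    touch_cor <- tabulate(c(pi_[close_pair & cor_mask[pj]],
                            pj[close_pair & cor_mask[pi_]]), nbins = n) > 0
    new_subtype <- differentiation_step(cells$subtype, cells$strat_time_h,
                                        n_stem_nb, colony, dist_stem,
                                        cells$stage_time_h, touch_cor, cfg)
    changed <- which(!is.na(new_subtype) & new_subtype != cells$subtype)
    if (length(changed)) {
      events$differentiation <- data.frame(
        iteration = it, event = "differentiation",
        cell_id = cells$id[changed], z = cells$z[changed])
      cells$subtype[changed] <- new_subtype[changed]
      cells$stage_time_h[changed] <- 0
    }
    shed <- which(is.na(new_subtype))
    if (length(shed)) {
      events$desquamation <- data.frame(
        iteration = it, event = "desquamation",
        cell_id = cells$id[shed], z = cells$z[shed])
    }

    # active migration of TA cells attached to the sheet, applied in a
    # shuffled order against current positions; moves into occupied
    # territory are cancelled (contact inhibition of locomotion)
    ta_idx <- which(cells$subtype == SUBTYPE_LEVELS[["TA"]] & deg_bond > 0)
    if (length(ta_idx)) {
      ta_idx <- ta_idx[sample.int(length(ta_idx))]
      pm_tiles <- which(tile_class(world$tiles$ecm_value) ==
                          TILE_CLASS_CODES[["PM"]])
      px <- world$tiles$cx[pm_tiles]; py <- world$tiles$cy[pm_tiles]
      step_len <- cfg$migration_speed * cfg$dt_min
      for (i in ta_idx) {
        theta <- runif(1, 0, 2 * pi)
        dir2 <- c(cos(theta), sin(theta))
        if (length(pm_tiles)) {
          dx <- px - cells$x[i]; dy <- py - cells$y[i]
          d <- sqrt(dx^2 + dy^2)
          m <- which.min(d)
          if (d[m] <= cfg$sensing_radius && d[m] > 1e-12 &&
              runif(1) < cfg$p_bias) {
            dir2 <- c(dx[m], dy[m]) / d[m]
          }
        }
        tx <- cells$x[i] + dir2[1] * step_len
        ty <- cells$y[i] + dir2[2] * step_len
        d2 <- (cells$x - tx)^2 + (cells$y - ty)^2 + (cells$z - cells$z[i])^2
        d2[i] <- Inf
        if (min(d2) >= (2 * CELL_RADIUS)^2) {
          cells$x[i] <- tx
          cells$y[i] <- ty
        }
      }
    }

    # remove desquamated corneocytes
    if (length(shed)) {
      keep <- setdiff(seq_len(n), shed)
      cells <- cells[keep, , drop = FALSE]
      world$cell_store <- world$cell_store[keep, , drop = FALSE]
    }
  }

  if (!is.null(daughters)) {
    cells <- rbind(cells, daughters)
    world$cell_store <- rbind(world$cell_store, daughter_store)
  }
  rownames(cells) <- NULL
  world$cells <- cells

  ## ---- (4) physics ----
  world <- resolve_overlaps(world, quiet = quiet,
                            seed = sample.int(.Machine$integer.max, 1))
  world$last_resolve <- attr(world, "resolve")
  attr(world, "resolve") <- NULL

  ## ---- bookkeeping ----
  world$iteration <- it + 1L
  keep_from <- world$iteration - cfg$plateau_window
  world$division_log <- world$division_log[
    world$division_log$iteration > keep_from, , drop = FALSE]
  world$last_ledger <- ledger
  world$last_events <- if (length(events)) do.call(rbind, events) else
    data.frame(iteration = integer(0), event = character(0),
               cell_id = integer(0), z = numeric(0))
  rownames(world$last_events) <- NULL
  world$rng_state <- get(".Random.seed", envir = globalenv())
  world
}

# connected stem-colony size per cell (0 for non-stems), union-find over
# stem-stem contact pairs
stem_colony_sizes <- function(n, stem_idx, stem_pairs) {
  sizes <- numeric(n)
  if (!length(stem_idx)) return(sizes)
  stem_idx <- as.integer(stem_idx)
  if (length(stem_pairs)) storage.mode(stem_pairs) <- "integer"
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(stem_pairs)) {
    for (k in seq_len(nrow(stem_pairs))) {
      a <- find(stem_pairs[k, 1]); b <- find(stem_pairs[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(stem_idx, find, integer(1))
  tab <- table(roots)
  sizes[stem_idx] <- as.integer(tab[as.character(roots)])
  sizes
}

#' Grow a virtual epidermis
#'
#' Seeds the world and iterates [step_world()] until the stop rule fires:
#' either a fixed number of iterations, or the homeostatic plateau (the total
#' cell count changes by less than `plateau_frac` over a sliding
#' `plateau_window` of iterations), subject to `max_iterations`.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed for the whole run.
#' @param iterations Number of iterations when `stop_rule = "iterations"`.
#' @param stop_rule `"iterations"` or `"plateau"`.
#' @param max_iterations Hard cap for the plateau rule.
#' @param snapshot_every Write a snapshot every this many iterations
#'   (0 = none); requires `out_dir`.
#' @param out_dir Directory for snapshot and log output.
#' @param world Optionally continue from an existing world instead of
#'   seeding a fresh one.
#' @param quiet Suppress per-100-iteration progress lines.
#' @return An object of class `epi_run`: list with `census` (one row per
#'   iteration), `events`, `final_world`, `config`, `config_hash`, `seed`,
#'   `iterations_run`, `plateau_iteration` (NA if the rule never fired),
#'   `record_hash`.
#' @export
run_epidermis <- function(config = sim_config(), seed = 1L, iterations = NULL,
                          stop_rule = c("iterations", "plateau"),
                          max_iterations = 6000L, snapshot_every = 0L,
                          out_dir = NULL, world = NULL, quiet = TRUE) {
  stop_rule <- match.arg(stop_rule)
  if (stop_rule == "iterations" && is.null(iterations)) {
    stop("run_epidermis(): iterations must be given for the iteration rule")
  }
  if (snapshot_every > 0 && is.null(out_dir)) {
    stop("run_epidermis(): snapshot_every needs out_dir")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (is.null(world)) {
    world <- seed_world(config$n_seed_stem, config$lx, config$ly, seed, config)
  }
  limit <- if (stop_rule == "iterations") iterations else max_iterations

  census_rows <- vector("list", limit + 1L)
  census_rows[[1]] <- census_row(world)
  events <- list()
  counts <- integer(limit + 1L)
  counts[1] <- nrow(world$cells)
  plateau_iteration <- NA_integer_
  i <- 0L
  while (i < limit) {
    i <- i + 1L
    world <- step_world(world, config, quiet = TRUE)
    if (!world$last_resolve$converged &&
        world$last_resolve$max_overlap > 10 * config$phys_tol && !quiet) {
      message("iteration ", world$iteration,
              ": residual overlap ",
              signif(world$last_resolve$max_overlap, 3), " um after ",
              world$last_resolve$sweeps, " sweeps")
    }
    census_rows[[i + 1L]] <- census_row(world)
    counts[i + 1L] <- nrow(world$cells)
    if (nrow(world$last_events)) events[[length(events) + 1L]] <- world$last_events
    if (snapshot_every > 0 && world$iteration %% snapshot_every == 0L) {
      write_snapshot(world, file.path(out_dir,
                                      sprintf("snapshot_%06d.tsv",
                                              world$iteration)))
    }
    if (!quiet && i %% 100L == 0L) {
      cs <- census(world)
      message(sprintf("iteration %d: %d cells (%s)", world$iteration,
                      cs$n_cells,
                      paste(names(cs$subtype_counts), cs$subtype_counts,
                            sep = "=", collapse = " ")))
    }
    if (stop_rule == "plateau" && i >= config$plateau_window) {
      win <- counts[(i + 1L - config$plateau_window):(i + 1L)]
      if (max(win) > 0 &&
          (max(win) - min(win)) <= config$plateau_frac * max(win)) {
        plateau_iteration <- world$iteration
        break
      }
    }
  }
  census_df <- do.call(rbind, census_rows[!vapply(census_rows, is.null,
                                                  logical(1))])
  rownames(census_df) <- NULL
  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(iteration = integer(0), event = character(0),
               cell_id = integer(0), z = numeric(0))
  rownames(events_df) <- NULL
  rec <- structure(list(
    census = census_df,
    events = events_df,
    final_world = world,
    config = config,
    config_hash = config_hash(config),
    seed = seed,
    iterations_run = i,
    plateau_iteration = plateau_iteration
  ), class = "epi_run")
  rec$record_hash <- run_record_hash(rec)
  if (!is.null(out_dir)) {
    write.table(census_df, file.path(out_dir, "census.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(events_df, file.path(out_dir, "events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("seed = %d", seed),
                 sprintf("config_hash = %s", rec$config_hash),
                 sprintf("iterations_run = %d", i),
                 sprintf("plateau_iteration = %s", plateau_iteration),
                 sprintf("record_hash = %s", rec$record_hash)),
               file.path(out_dir, "run_metadata.txt"))
  }
  rec
}

census_row <- function(world) {
  subtype <- tabulate(world$cells$subtype + 1L, nbins = 4L)
  cls <- tile_class(world$tiles$ecm_value)
  data.frame(
    iteration = world$iteration,
    n_cells = nrow(world$cells),
    stem = subtype[1], TA = subtype[2], committed = subtype[3],
    corneocyte = subtype[4],
    bm_tiles = sum(cls == TILE_CLASS_CODES[["BM"]]),
    sm_tiles = sum(cls == TILE_CLASS_CODES[["SM"]]),
    pm_tiles = sum(cls == TILE_CLASS_CODES[["PM"]]),
    total_agents = nrow(world$cells) + nrow(world$tiles) + 1L
  )
}

# stable hash of a run record: census + final snapshot text
run_record_hash <- function(rec) {
  txt <- paste(
    paste(capture_table(rec$census), collapse = "\n"),
    paste(snapshot_lines(rec$final_world), collapse = "\n"),
    sep = "\n--\n")
  fnv1a64(txt)
}

capture_table <- function(df) {
  apply(df, 1, function(r) paste(format(r, digits = 15), collapse = "\t"))
}

#' @export
print.epi_run <- function(x, ...) {
  cat("<epi_run> seed ", x$seed, ", ", x$iterations_run, " iterations",
      if (!is.na(x$plateau_iteration)) paste0(" (plateau at ",
                                              x$plateau_iteration, ")"),
      "\n", sep = "")
  print(x$final_world)
  invisible(x)
}

#' Wound a grown epidermis and run healing to closure
#'
#' Applies [wound_world()] and keeps stepping until the wound has closed --
#' no tile is still provisional-matrix class and the cell count has
#' recovered to at least 80% of its pre-wound value -- or the iteration
#' budget runs out. Budget exhaustion is recorded as non-closure, not an
#' error.
#'
#' @param config A [sim_config()].
#' @param wound_box Numeric `c(x0, y0, z0, x1, y1, z1)` passed to
#'   [wound_world()].
#' @param grown A grown world (`epi_world`) or run (`epi_run`).
#' @param budget Maximum healing iterations.
#' @param recovery_fraction Cell-count recovery defining closure (0.8).
#' @param quiet Suppress progress output.
#' @return A list: `closed` (logical), `closure_iteration` (iterations after
#'   wounding; NA when not closed), `pre_wound_cells`, `wounded_cells`,
#'   `final_world`, `census` (per-iteration rows after wounding), `events`.
#' @export
heal_experiment <- function(config, wound_box, grown, budget = 5000L,
                            recovery_fraction = 0.8, quiet = TRUE) {
  world <- if (inherits(grown, "epi_run")) grown$final_world else grown
  stopifnot(inherits(world, "epi_world"))
  pre <- nrow(world$cells)
  world <- wound_world(world, wound_box)
  wounded <- nrow(world$cells)

  closed_now <- function(w) {
    all(tile_class(w$tiles$ecm_value) != TILE_CLASS_CODES[["PM"]]) &&
      nrow(w$cells) >= recovery_fraction * pre
  }
  census_rows <- list(census_row(world))
  events <- list()
  closure <- NA_integer_
  if (closed_now(world)) {
    closure <- 0L
  } else {
    for (i in seq_len(budget)) {
      world <- step_world(world, config, quiet = TRUE)
      census_rows[[i + 1L]] <- census_row(world)
      if (nrow(world$last_events)) {
        events[[length(events) + 1L]] <- world$last_events
      }
      if (!quiet && i %% 100L == 0L) {
        message("healing iteration ", i, ": ", nrow(world$cells), " cells, ",
                sum(tile_class(world$tiles$ecm_value) ==
                      TILE_CLASS_CODES[["PM"]]), " PM tiles")
      }
      if (closed_now(world)) { closure <- i; break }
    }
  }
  census_df <- do.call(rbind, census_rows)
  rownames(census_df) <- NULL
  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(iteration = integer(0), event = character(0),
               cell_id = integer(0), z = numeric(0))
  list(closed = !is.na(closure), closure_iteration = closure,
       pre_wound_cells = pre, wounded_cells = wounded,
       final_world = world, census = census_df, events = events_df)
}
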