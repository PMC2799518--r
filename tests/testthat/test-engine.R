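test_that("an empty world steps to an empty world", {
  cfg <- sim_config(lx = 40, ly = 40, n_seed_stem = 0)
  w <- seed_world(0, 40, 40, seed = 1, config = cfg)
  w2 <- step_world(w)
  expect_equal(nrow(w2$cells), 0)
  expect_equal(w2$iteration, 1L)
  expect_equal(w2$last_ledger$produced, 0)
})

test_that("a lone basal stem cell on BM is fully suppressed", {
  cfg <- sim_config(lx = 40, ly = 40, n_seed_stem = 1)
  w <- seed_world(1, 40, 40, seed = 2, config = cfg)
  w2 <- step_world(w)
  # BM contact suppresses the promoter chain: no mRNA, no latent produced
  expect_equal(w2$cells$PRO, 0)
  expect_equal(w2$cells$mRNA, 0)
  expect_equal(w2$last_ledger$produced, 0)
  expect_equal(sum(w2$tile_store), 0)
})

test_that("replays with the same seed are byte-identical", {
  cfg <- sim_config(lx = 60, ly = 60, n_seed_stem = 8)
  runs <- lapply(1:2, function(k) {
    w <- seed_world(8, 60, 60, seed = 31, config = cfg)
    for (i in 1:100) w <- step_world(w, quiet = TRUE)
    w
  })
  f1 <- tempfile(); f2 <- tempfile()
  write_snapshot(runs[[1]], f1)
  write_snapshot(runs[[2]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the TGF-beta1 mass ledger closes every iteration", {
  cfg <- sim_config(lx = 60, ly = 60, n_seed_stem = 10)
  w <- seed_world(10, 60, 60, seed = 5, config = cfg)
  # wound half the surface so PM tiles drive real production/activation
  w <- wound_world(w, c(0, 0, 0, 30, 60, 100))
  for (i in 1:60) {
    w <- step_world(w, quiet = TRUE)
    led <- w$last_ledger
    expect_lt(abs(led$produced -
                    (led$deposited + led$credited + led$discarded)), 1e-9)
    expect_lt(abs(led$retrieved -
                    (led$activated + led$activation_loss)), 1e-9)
  }
  # something actually flowed
  expect_gt(w$last_ledger$produced + sum(w$tile_store), 0)
})

test_that("tile ECM values never increase except at wound events", {
  cfg <- sim_config(lx = 60, ly = 60, n_seed_stem = 10)
  w <- seed_world(10, 60, 60, seed = 6, config = cfg)
  w <- wound_world(w, c(0, 0, 0, 60, 30, 100))
  prev <- w$tiles$ecm_value
  for (i in 1:80) {
    w <- step_world(w, quiet = TRUE)
    expect_true(all(w$tiles$ecm_value <= prev + 1e-12))
    prev <- w$tiles$ecm_value
  }
})

test_that("no membrane or tile parcel survives past the 48-h lifetime", {
  cfg <- sim_config(lx = 40, ly = 40, n_seed_stem = 6)
  w <- seed_world(6, 40, 40, seed = 7, config = cfg)
  L <- epidermabm:::lifetime_iterations(cfg)
  for (i in 1:(L + 10)) w <- step_world(w, quiet = TRUE)
  # reconstruct parcel ages from the ring stores
  for (store in list(w$cell_store, w$tile_store)) {
    for (r in seq_len(nrow(store))) {
      p <- epidermabm:::ring_to_parcels(store, r, w$iteration - 1L, cfg)
      if (nrow(p)) {
        expect_true(all(w$iteration - 1L - p$deposit_iteration < L))
      }
    }
  }
})

test_that("agents change only through division, differentiation and wounds", {
  cfg <- sim_config(lx = 60, ly = 60, n_seed_stem = 10)
  w <- seed_world(10, 60, 60, seed = 8, config = cfg)
  for (i in 1:150) {
    before <- nrow(w$cells)
    ids_before <- w$cells$id
    w <- step_world(w, quiet = TRUE)
    ev <- w$last_events
    births <- sum(ev$event == "division")
    deaths <- sum(ev$event == "desquamation")
    expect_equal(nrow(w$cells), before + births - deaths)
    expect_false(anyDuplicated(w$cells$id) > 0)
    # survivors keep their identity
    expect_true(all(setdiff(ids_before, ev$cell_id[ev$event ==
                                                     "desquamation"]) %in%
                      w$cells$id))
  }
})

test_that("run records census per iteration and a stable hash", {
  cfg <- sim_config(lx = 40, ly = 40, n_seed_stem = 5)
  rec0 <- run_epidermis(cfg, seed = 9, iterations = 0)
  expect_equal(nrow(rec0$census), 1)  # only the initial census
  rec <- run_epidermis(cfg, seed = 9, iterations = 40)
  expect_equal(nrow(rec$census), 41)
  expect_equal(rec$census$n_cells[1], 5)
  expect_match(rec$record_hash, "^[0-9a-f]{16}$")
  rec2 <- run_epidermis(cfg, seed = 9, iterations = 40)
  expect_identical(rec$record_hash, rec2$record_hash)
  rec3 <- run_epidermis(cfg, seed = 10, iterations = 40)
  expect_false(identical(rec$record_hash, rec3$record_hash))
})

test_that("run can write snapshots, census and metadata to disk", {
  cfg <- sim_config(lx = 40, ly = 40, n_seed_stem = 5)
  out <- file.path(tempdir(), "epirun-test")
  rec <- run_epidermis(cfg, seed = 12, iterations = 20, snapshot_every = 10,
                       out_dir = out)
  expect_true(file.exists(file.path(out, "census.tsv")))
  expect_true(file.exists(file.path(out, "run_metadata.txt")))
  snaps <- list.files(out, pattern = "^snapshot_")
  expect_length(snaps, 2)
  df <- read_snapshot(file.path(out, snaps[1]))
  expect_equal(sum(df$agent_kind == "tile"), 4)
  unlink(out, recursive = TRUE)
})

test_that("a zero-size wound heals instantly", {
  cfg <- sim_config(lx = 40, ly = 40, n_seed_stem = 6)
  grown <- run_epidermis(cfg, seed = 13, iterations = 30)
  heal <- heal_experiment(cfg, c(0, 0, 0, 0, 0, 0), grown, budget = 10)
  expect_true(heal$closed)
  expect_equal(heal$closure_iteration, 0L)
  expect_equal(heal$wounded_cells, heal$pre_wound_cells)
})

test_that("healing always reports an outcome within its budget", {
  cfg <- sim_config(lx = 40, ly = 40, n_seed_stem = 8)
  grown <- run_epidermis(cfg, seed = 14, iterations = 60)
  heal <- heal_experiment(cfg, c(0, 0, 0, 40, 40, 100), grown, budget = 5)
  expect_false(heal$closed)           # a 5-iteration budget cannot close it
  expect_true(is.na(heal$closure_iteration))
  expect_equal(nrow(heal$census), 6)  # initial + budget rows
})

test_that("the command-line interface runs grow and census end to end", {
  out <- file.path(tempdir(), "epicli-test")
  cfgf <- file.path(tempdir(), "cli.cfg")
  write_sim_config(sim_config(lx = 40, ly = 40, n_seed_stem = 5), cfgf)
  expect_invisible(epidermabm_cli(c("grow", "--config", cfgf, "--seed", "3",
                                    "--iterations", "10", "--stop-rule",
                                    "iterations", "--out", out, "--quiet")))
  expect_true(file.exists(file.path(out, "final_snapshot.tsv")))
  expect_output(
    epidermabm_cli(c("census", "--snapshot",
                     file.path(out, "final_snapshot.tsv"))),
    "agents:")
  expect_error(epidermabm_cli(c("explode")), "unknown subcommand")
  unlink(out, recursive = TRUE)
})
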