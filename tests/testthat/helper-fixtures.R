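# Shared fixtures, built in code.

# a small world: 4 tiles (40 x 40 um), a handful of stem cells
small_world <- function(n_stem = 4, seed = 42, ...) {
  cfg <- sim_config(lx = 40, ly = 40, n_seed_stem = n_stem, ...)
  seed_world(n_stem, 40, 40, seed = seed, config = cfg)
}

# independent reference integration of the trafficking network with deSolve
lsoda_oracle <- function(state, params, dt_min = 30) {
  rhs <- function(t, y, p) {
    vb <- p$k_bind * y[1] * y[2] * y[3]
    list(c(
      -vb,
      p$prod_r1 - vb - p$k_int_receptor * y[2] + p$k_recycle * y[6],
      p$prod_r2 - vb - p$k_int_receptor * y[3] + p$k_recycle * y[7],
      vb - (p$k_int_complex + p$k_deg_complex) * y[4],
      p$k_int_complex * y[4] - p$k_deg_complex * y[5],
      p$k_int_receptor * y[2] - (p$k_recycle + p$k_deg_receptor) * y[6],
      p$k_int_receptor * y[3] - (p$k_recycle + p$k_deg_receptor) * y[7]
    ))
  }
  out <- deSolve::lsoda(unname(state), c(0, dt_min), rhs, params,
                        rtol = 1e-11, atol = 1e-13)
  setNames(out[2, -1], names(state))
}

# random nonnegative trafficking parameter draw within the documented ranges
random_trafficking_params <- function() {
  trafficking_params(
    k_bind = runif(1, 1e-4, 2e-3),
    k_int_complex = runif(1, 0.05, 0.5),
    k_int_receptor = runif(1, 0.02, 0.3),
    k_recycle = runif(1, 0.02, 0.3),
    k_deg_complex = runif(1, 0.01, 0.3),
    k_deg_receptor = runif(1, 0.01, 0.2),
    prod_r1 = runif(1, 0, 1),
    prod_r2 = runif(1, 0, 1)
  )
}

random_state <- function() {
  subcellular_state(ligand = runif(1, 0, 120), R1 = runif(1, 0, 40),
                    R2 = runif(1, 0, 40), LRCP = runif(1, 0, 25),
                    LRCE = runif(1, 0, 25), R1E = runif(1, 0, 20),
                    R2E = runif(1, 0, 20))
}

# grow the reference epidermis (30 stem cells, 100 x 100 um, plateau stop
# rule) once per test session and share it between the acceptance blocks
.test_cache <- new.env(parent = emptyenv())
grown_run <- function() {
  if (is.null(.test_cache$grown)) {
    cfg <- sim_config()
    .test_cache$grown <- run_epidermis(cfg, seed = 101, stop_rule = "plateau",
                                       max_iterations = 4000, quiet = TRUE)
  }
  .test_cache$grown
}

# canonical snapshot text of a run's final world
snapshot_lines_of <- function(rec) {
  f <- tempfile()
  write_snapshot(rec$final_world, f)
  on.exit(unlink(f))
  readLines(f)
}
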