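test_that("tile weights follow the ECM classification bands", {
  w <- tile_weights(c(0, 0.05, 0.1, 0.3, 0.49, 0.5, 0.8, 1))
  expect_equal(w$BM, c(1, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(w$SM, c(0, 0, 0.1, 0.3, 0.49, 0, 0, 0))
  expect_equal(w$PM, c(0, 0, 0, 0, 0, 0.5, 0.8, 1))
  # at most one weight nonzero
  expect_true(all(rowSums(w > 0) <= 1))
  expect_error(tile_weights(1.2), "\\[0, 1\\]")
  expect_error(tile_weights(-0.1), "\\[0, 1\\]")
})

test_that("promoter activity reproduces the coefficient worked examples", {
  cfg <- sim_config()
  # PM contact, no ligand, basal: delta * xi * PM = 10
  expect_equal(promoter_activity(tile_weights(1), TRUE, 0, 0, cfg), 10)
  # full BM suppression regardless of ligand
  expect_equal(promoter_activity(tile_weights(0), TRUE, 20, 0, cfg), 0)
  # detached stratified cell: phi * LRCP + D_w = 0.4 * 20 + 1 = 9
  expect_equal(promoter_activity(tile_weights(0), FALSE, 20, 15, cfg), 9)
  expect_error(promoter_activity(tile_weights(0.3), TRUE, -1, 0, cfg), ">= 0")
})

test_that("promoter activity is monotone in each signal", {
  cfg <- sim_config()
  set.seed(1)
  for (k in 1:50) {
    e <- runif(1)
    lrcp <- runif(1, 0, 50)
    d <- runif(1, 0, 40)
    base <- promoter_activity(tile_weights(e), TRUE, lrcp, d, cfg)
    expect_gte(promoter_activity(tile_weights(e), TRUE, lrcp + 1, d, cfg), base)
    expect_gte(promoter_activity(tile_weights(e), TRUE, lrcp, d + 15, cfg), base)
    expect_gte(base, 0)
  }
  # increasing PM weight raises PRO
  expect_gt(promoter_activity(tile_weights(0.9), TRUE, 0, 0, cfg),
            promoter_activity(tile_weights(0.6), TRUE, 0, 0, cfg))
})

test_that("transcription/translation is linear below the cap, capped above", {
  cfg <- sim_config()
  tt <- transcribe_translate(1, cfg)
  expect_equal(tt$mRNA, 5)
  expect_equal(tt$latent, 25)
  expect_equal(transcribe_translate(0, cfg), list(mRNA = 0, latent = 0))
  big <- transcribe_translate(10, cfg)
  expect_equal(big$mRNA, 50)
  expect_equal(big$latent, 200)  # capped, never exceeded
  # exact attainment boundary: cap / (Phi * Omega) = 8
  pro <- seq(0, 20, by = 0.25)
  lat <- transcribe_translate(pro, cfg)$latent
  expect_true(all(lat <= 200))
  expect_equal(lat[pro >= 8], rep(200, sum(pro >= 8)))
  expect_equal(lat[pro < 8], 25 * pro[pro < 8])
})

test_that("deterministic trafficking matches the stiff-integrator oracle", {
  skip_if_not_installed("deSolve")
  p <- trafficking_params()
  s0 <- wound_start_state()
  mine <- trafficking_step(s0, p)
  ref <- lsoda_oracle(s0, p)
  expect_lt(max(abs(mine - ref) / pmax(abs(ref), 1e-6)), 1e-6)

  set.seed(20)
  worst <- 0
  for (k in 1:25) {
    pp <- random_trafficking_params()
    ss <- random_state()
    mine <- trafficking_step(ss, pp)
    ref <- lsoda_oracle(ss, pp)
    worst <- max(worst, max(abs(mine - ref) / pmax(abs(ref), 1e-6)))
  }
  expect_lt(worst, 1e-6)
})

test_that("trafficking preserves nonnegativity and conservation laws", {
  # no ligand, no complexes: none appear
  p <- trafficking_params()
  s <- subcellular_state(ligand = 0, LRCP = 0, LRCE = 0)
  out <- trafficking_step(s, p)
  expect_equal(out[["LRCP"]], 0)
  expect_equal(out[["LRCE"]], 0)
  # with degradation and production off, receptor material is conserved
  p0 <- trafficking_params(k_deg_complex = 0, k_deg_receptor = 0,
                           prod_r1 = 0, prod_r2 = 0)
  s0 <- wound_start_state()
  out0 <- trafficking_step(s0, p0)
  r1_before <- s0[["R1"]] + s0[["R1E"]] + s0[["LRCP"]] + s0[["LRCE"]]
  r1_after <- out0[["R1"]] + out0[["R1E"]] + out0[["LRCP"]] + out0[["LRCE"]]
  expect_lt(abs(r1_after - r1_before), 1e-9)
  r2_before <- s0[["R2"]] + s0[["R2E"]] + s0[["LRCP"]] + s0[["LRCE"]]
  r2_after <- out0[["R2"]] + out0[["R2E"]] + out0[["LRCP"]] + out0[["LRCE"]]
  expect_lt(abs(r2_after - r2_before), 1e-9)
  # property sweep: nonnegative everywhere, no clipping required
  set.seed(33)
  for (k in 1:40) {
    out <- trafficking_step(random_state(), random_trafficking_params())
    expect_true(all(out >= 0))
  }
})

test_that("normal-condition receptor pools are a rest state of the cycle", {
  p <- trafficking_params()
  s <- subcellular_state(ligand = 0)
  out <- trafficking_step(s, p)
  expect_equal(out[["R1"]], 20, tolerance = 1e-8)
  expect_equal(out[["R1E"]], 10, tolerance = 1e-8)
  expect_equal(out[["R2"]], 20, tolerance = 1e-8)
  expect_equal(out[["R2E"]], 10, tolerance = 1e-8)
})

test_that("stochastic trafficking agrees with the deterministic mean", {
  p <- trafficking_params()
  s0 <- wound_start_state()
  det <- trafficking_step(s0, p)
  n_rep <- 1000
  vol <- 2000  # large-count scaling
  set.seed(5)
  mat <- matrix(rep(s0, each = n_rep), nrow = n_rep)
  colnames(mat) <- names(s0)
  out <- trafficking_step(mat, p, mode = "stochastic", volume = vol)
  for (sp in colnames(out)) {
    m <- mean(out[, sp]); se <- sd(out[, sp]) / sqrt(n_rep)
    expect_lt(abs(m - det[[sp]]), 3 * se + 0.02,
              label = paste0(sp, ": |", signif(m, 4), " - ", signif(det[[sp]], 4),
                             "| vs 3se = ", signif(3 * se, 3)))
  }
})

test_that("bond strengths recover defaults at zero signal and weaken with it", {
  cfg <- sim_config()
  b0 <- bond_strengths(0, cfg)
  expect_equal(b0$IN, 0); expect_equal(b0$PR, 0)
  expect_equal(b0$CCB, cfg$ccb0); expect_equal(b0$CSB, cfg$csb0)
  b <- bond_strengths(20, cfg)
  expect_equal(b$IN, 10)  # Pi = 0.5
  expect_equal(b$PR, 10)
  # CCB strictly decreasing in LRCE
  lrce <- seq(0, 50, by = 0.5)
  ccb <- bond_strengths(lrce, cfg)$CCB
  expect_true(all(diff(ccb) < 0))
  csb <- bond_strengths(lrce, cfg)$CSB
  expect_true(all(csb > 0 & is.finite(csb)))
  expect_error(bond_strengths(-1, cfg), ">= 0")
})

test_that("negative trafficking rates are a configuration error", {
  expect_error(trafficking_params(k_bind = -0.1), ">= 0")
  expect_error(trafficking_params(nonsense = 1), "unknown")
})
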