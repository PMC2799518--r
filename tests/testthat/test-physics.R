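test_that("pair force follows the overlap/bond/zero regimes", {
  p <- force_params()
  # overlap 2 um at centre distance 8 -> repulsion 2 * k_rep along x
  f <- pair_force(c(0, 0, 0), c(8, 0, 0), 1, p)
  expect_equal(f, c(-2 * p$k_rep, 0, 0))
  # gap 6 um > bond range -> zero
  expect_equal(pair_force(c(0, 0, 0), c(16, 0, 0), 1, p), c(0, 0, 0))
  # gap in (0, 5]: attraction toward the partner, scaled by CCB
  fa <- pair_force(c(0, 0, 0), c(12.5, 0, 0), 2, p)
  expect_equal(fa, c(p$k_att * 2 * 2.5 / 5, 0, 0))
  expect_gt(fa[1], 0)  # pulled toward +x
})

test_that("pair force is antisymmetric for random configurations", {
  p <- force_params()
  set.seed(14)
  for (k in 1:50) {
    a <- runif(3, 0, 30); b <- a + runif(3, -12, 12)
    ccb <- runif(1, 0.2, 2)
    expect_equal(pair_force(a, b, ccb, p), -pair_force(b, a, ccb, p),
                 tolerance = 1e-12)
  }
  # coincident centres: finite repulsion of contact magnitude
  set.seed(15)
  f0 <- pair_force(c(1, 1, 1), c(1, 1, 1), 1, p)
  expect_equal(sqrt(sum(f0^2)), p$k_rep * 10, tolerance = 1e-9)
})

test_that("the bond cutoff sits exactly at a 5-um surface gap", {
  p <- force_params()
  att <- function(gap) {
    f <- pair_force(c(0, 0, 0), c(10 + gap, 0, 0), 1, p)
    f[1]
  }
  lo <- 0.1; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (att(mid) != 0) lo <- mid else hi <- mid
  }
  expect_equal(lo, 5, tolerance = 1e-9)
})

test_that("two overlapping spheres separate symmetrically to contact", {
  # closed-form oracle: equal spheres overlapping 2 um, no bonds/walls ->
  # final centre distance 10 um, midpoint unchanged
  pos <- rbind(c(50, 50, 50), c(58, 50, 50))
  p <- force_params(k_att = 1e-9, k_settle = 1e-12)
  res <- resolve_overlaps(pos, params = p, quiet = TRUE)
  d <- sqrt(sum((res$pos[1, ] - res$pos[2, ])^2))
  expect_equal(d, 10, tolerance = 10 * p$tol)
  expect_equal(colMeans(res$pos), colMeans(pos), tolerance = 1e-8)
  expect_lte(res$max_overlap, 10 * p$tol)
})

test_that("overlapping triplets resolve below the overlap bound", {
  p <- force_params(k_att = 1e-9, k_settle = 1e-12)
  # line and triangle configurations of mutually overlapping spheres
  line <- rbind(c(50, 50, 50), c(58, 50, 50), c(66, 50, 50))
  tri <- rbind(c(50, 50, 50), c(58, 50, 50), c(54, 56, 50))
  for (pos in list(line, tri)) {
    res <- resolve_overlaps(pos, params = p, quiet = TRUE)
    expect_lte(res$max_overlap, 10 * p$tol)
    # centroid preserved under pure internal repulsion
    expect_equal(colMeans(res$pos), colMeans(pos), tolerance = 1e-8)
  }
})

test_that("well-separated supported cells are a fixed point", {
  # cells resting on the substrate (supported), gaps > bond range
  pos <- rbind(c(20, 20, 5), c(50, 20, 5), c(20, 50, 5), c(60, 60, 5))
  res <- resolve_overlaps(pos, params = force_params(), lx = 100, ly = 100,
                          wall_height = 100, quiet = TRUE)
  expect_equal(res$pos, unname(pos), tolerance = 1e-12)
  expect_true(res$converged)
})

test_that("unsupported cells settle onto support", {
  # a floating cell sinks toward the substrate-bond zone
  res <- resolve_overlaps(rbind(c(50, 50, 18)), params = force_params(),
                          lx = 100, ly = 100, wall_height = 100, quiet = TRUE)
  expect_lte(res$pos[1, 3], 10)
  # a cell resting on another does not sink through it
  stack <- rbind(c(50, 50, 5), c(50, 50, 14.9))
  res2 <- resolve_overlaps(stack, params = force_params(), lx = 100,
                           ly = 100, wall_height = 100, quiet = TRUE)
  expect_gt(res2$pos[2, 3], 12)
})

test_that("floor and walls keep every centre inside the column", {
  set.seed(21)
  pos <- cbind(runif(40, -5, 105), runif(40, -5, 105), runif(40, -10, 120))
  res <- resolve_overlaps(pos, params = force_params(), lx = 100, ly = 100,
                          wall_height = 100, quiet = TRUE)
  expect_true(all(res$pos[, 3] >= 5 - 0.05))
  expect_true(all(res$pos[, 3] <= 100))
  expect_true(all(res$pos[, 1] >= 0 & res$pos[, 1] <= 100))
  expect_true(all(res$pos[, 2] >= 0 & res$pos[, 2] <= 100))
})

test_that("relaxation is deterministic and overlap decays monotonically", {
  set.seed(22)
  pos <- cbind(runif(25, 30, 70), runif(25, 30, 70), runif(25, 45, 60))
  p <- force_params(k_att = 1e-9, k_settle = 1e-12)
  r1 <- resolve_overlaps(pos, params = p, seed = 99, trace = TRUE,
                         quiet = TRUE)
  r2 <- resolve_overlaps(pos, params = p, seed = 99, trace = TRUE,
                         quiet = TRUE)
  expect_identical(r1$pos, r2$pos)
  # overlap energy (sum of squared overlaps) is non-increasing across
  # sweeps on a repulsion-only configuration
  tr <- r1$overlap_trace
  if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
})
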