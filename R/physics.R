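#' Mechanics parameters
#'
#' Coefficients of the overlapping-spheres force model: `k_rep` (repulsion
#' stiffness per um of overlap), `k_att` (attraction scale multiplying the
#' cell-cell bond strength CCB or cell-substrate bond strength CSB),
#' `mobility` (displacement per unit force per relaxation sweep, um), `tol`
#' (convergence threshold on the largest per-cell displacement, um) and
#' `max_sweeps`; `k_settle` is the constant downward force applied to cells
#' that have neither substrate contact nor a supporting neighbour below them
#' (unsupported cells settle onto support; resting stacks feel no extra
#' load). Stem cells additionally multiply their substrate bond by the
#' configuration's `stem_anchor` (basement-membrane anchoring).
#'
#' @param config A [sim_config()] supplying defaults.
#' @param ... name = value overrides.
#' @return An object of class `force_params`.
#' @export
force_params <- function(config = sim_config(), ...) {
  p <- list(k_rep = config$k_rep, k_att = config$k_att,
            mobility = config$mobility, tol = config$phys_tol,
            max_sweeps = as.integer(config$max_sweeps),
            bond_range = config$bond_range, k_settle = config$k_settle)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) {
    stop("force_params(): unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(overrides)] <- overrides
  for (k in names(p)) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || p[[k]] <= 0) {
      stop("force_params(): '", k, "' must be a single positive number")
    }
  }
  p$max_sweeps <- as.integer(p$max_sweeps)
  structure(p, class = "force_params")
}

#' Pairwise force between two cells
#'
#' Cells are rigid 10-um-diameter spheres, so contact is at centre distance
#' 10 um. Overlapping cells (`d < 10`) repel along the centre line with
#' magnitude `k_rep * (10 - d)`; cells with a surface gap in (0, 5] um feel a
#' bond attraction `k_att * CCB * gap / 5` toward each other; beyond a 5-um
#' gap the force is zero. The force is antisymmetric:
#' `pair_force(a, b) = -pair_force(b, a)`. Coincident centres repel along a
#' random unit vector drawn from R's RNG stream so that runs stay
#' reproducible.
#'
#' @param pos_a,pos_b Length-3 positions, um.
#' @param ccb Cell-cell bond strength used for the attractive branch (for two
#'   cells with different bond strengths the engine uses their mean).
#' @param params A [force_params()].
#' @return Length-3 force on the cell at `pos_a`.
#' @export
#' @examples
#' p <- force_params()
#' pair_force(c(0, 0, 0), c(8, 0, 0), 1, p)   # overlap 2 -> repulsion 2*k_rep
#' pair_force(c(0, 0, 0), c(16, 0, 0), 1, p)  # gap 6 > 5 -> zero
pair_force <- function(pos_a, pos_b, ccb = 1, params = force_params()) {
  stopifnot(length(pos_a) == 3, length(pos_b) == 3)
  delta <- pos_a - pos_b
  d <- sqrt(sum(delta^2))
  contact <- 2 * CELL_RADIUS
  if (d < 1e-9) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    return(params$k_rep * contact * u)
  }
  u <- delta / d
  if (d < contact) {
    params$k_rep * (contact - d) * u
  } else {
    gap <- d - contact
    if (gap <= params$bond_range) {
      -params$k_att * ccb * (gap / params$bond_range) * u
    } else {
      c(0, 0, 0)
    }
  }
}

#' Resolve overlaps and bonds in a world
#'
#' Damped relaxation of the whole cell collection: every sweep sums pair
#' forces (repulsion on overlap, bond attraction within the 5-um gap, using
#' each pair's mean CCB), substrate adhesion scaled by each cell's CSB, and
#' one-sided spring forces from the floor, the four walls and the wall top,
#' then moves every cell by `mobility * force`. Sweeps repeat until the
#' largest per-cell displacement falls below `tol` or `max_sweeps` is
#' reached; non-convergence is a warning, never an error.
#'
#' @param world An `epi_world`, or a bare n x 3 position matrix (then `lx`,
#'   `ly`, `wall_height`, `ccb`, `csb` may be given explicitly).
#' @param params A [force_params()]; defaults to the world's configuration.
#' @param ccb,csb Bond strengths (recycled); default from the world's cells.
#' @param lx,ly,wall_height Domain geometry when `world` is a bare matrix.
#' @param seed Seed for the degenerate-direction tie-break stream.
#' @param trace Record the residual overlap energy (sum of squared
#'   overlaps) after each sweep.
#' @param quiet Suppress the non-convergence warning.
#' @return For a world input: the world with resolved positions (and the
#'   solver diagnostics in `attr(, "resolve")`). For a matrix input: a list
#'   with `pos`, `sweeps`, `converged`, `max_overlap`, `overlap_trace`.
#' @export
resolve_overlaps <- function(world, params = NULL, ccb = NULL, csb = NULL,
                             lx = NULL, ly = NULL, wall_height = NULL,
                             seed = NULL, trace = FALSE, quiet = FALSE) {
  if (inherits(world, "epi_world")) {
    cfg <- world$config
    if (is.null(params)) params <- force_params(cfg)
    pos <- as.matrix(world$cells[, c("x", "y", "z")])
    ccb <- world$cells$CCB
    csb <- world$cells$CSB
    anchor <- ifelse(world$cells$subtype == SUBTYPE_LEVELS[["stem"]],
                     cfg$stem_anchor, 1)
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
    res <- resolve_cpp(pos, ccb, csb, anchor, params$k_rep, params$k_att,
                       params$mobility, params$tol, params$max_sweeps,
                       params$bond_range, params$k_settle,
                       world$dims[["lx"]], world$dims[["ly"]],
                       world$wall_height, as.integer(seed), trace)
    if (!res$converged && res$max_overlap > 10 * params$tol && !quiet) {
      warning("resolve_overlaps(): residual overlap ",
              signif(res$max_overlap, 3), " um after ", res$sweeps,
              " sweeps", call. = FALSE)
    }
    world$cells$x <- res$pos[, 1]
    world$cells$y <- res$pos[, 2]
    world$cells$z <- res$pos[, 3]
    attr(world, "resolve") <- res[c("sweeps", "converged", "max_overlap",
                                    "overlap_trace")]
    world
  } else {
    pos <- as.matrix(world)
    stopifnot(ncol(pos) == 3)
    n <- nrow(pos)
    if (is.null(params)) params <- force_params()
    if (is.null(ccb)) ccb <- rep(1, n)
    if (is.null(csb)) csb <- rep(1, n)
    if (is.null(lx)) lx <- 1e6
    if (is.null(ly)) ly <- 1e6
    if (is.null(wall_height)) wall_height <- 1e6
    if (is.null(seed)) seed <- 1L
    res <- resolve_cpp(pos, rep_len(ccb, n), rep_len(csb, n), rep(1, n),
                       params$k_rep, params$k_att, params$mobility,
                       params$tol, params$max_sweeps, params$bond_range,
                       params$k_settle, lx, ly, wall_height,
                       as.integer(seed), trace)
    if (!res$converged && res$max_overlap > 10 * params$tol && !quiet) {
      warning("resolve_overlaps(): residual overlap ",
              signif(res$max_overlap, 3), " um after ", res$sweeps,
              " sweeps", call. = FALSE)
    }
    res
  }
}
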