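SNAPSHOT_COLUMNS <- c("agent_id", "agent_kind", "subtype", "x", "y", "z",
                      "ECM_value", "R1", "R2", "LRCP", "LRCE", "R1E", "R2E",
                      "ligand", "PRO", "mRNA", "latent_store_total")

# snapshot body as a data.frame: one row per agent (cells, tiles, solver)
snapshot_table <- function(world) {
  cells <- world$cells
  n <- nrow(cells)
  cell_rows <- data.frame(
    agent_id = cells$id, agent_kind = "cell", subtype = cells$subtype,
    x = cells$x, y = cells$y, z = cells$z, ECM_value = NA_real_,
    R1 = cells$R1, R2 = cells$R2, LRCP = cells$LRCP, LRCE = cells$LRCE,
    R1E = cells$R1E, R2E = cells$R2E, ligand = cells$ligand,
    PRO = cells$PRO, mRNA = cells$mRNA,
    latent_store_total = if (n) ring_total(world$cell_store) else numeric(0)
  )
  tiles <- world$tiles
  tile_rows <- data.frame(
    agent_id = tiles$id, agent_kind = "tile",
    subtype = tile_class(tiles$ecm_value),
    x = tiles$cx, y = tiles$cy, z = 0, ECM_value = tiles$ecm_value,
    R1 = NA_real_, R2 = NA_real_, LRCP = NA_real_, LRCE = NA_real_,
    R1E = NA_real_, R2E = NA_real_, ligand = NA_real_, PRO = NA_real_,
    mRNA = NA_real_,
    latent_store_total = ring_total(world$tile_store)
  )
  solver_row <- data.frame(
    agent_id = 0L, agent_kind = "solver", subtype = 7L,
    x = NA_real_, y = NA_real_, z = NA_real_, ECM_value = NA_real_,
    R1 = NA_real_, R2 = NA_real_, LRCP = NA_real_, LRCE = NA_real_,
    R1E = NA_real_, R2E = NA_real_, ligand = NA_real_, PRO = NA_real_,
    mRNA = NA_real_, latent_store_total = NA_real_
  )
  out <- rbind(cell_rows, tile_rows, solver_row)
  rownames(out) <- NULL
  out[, SNAPSHOT_COLUMNS]
}

snapshot_lines <- function(world) {
  df <- snapshot_table(world)
  num <- vapply(df, is.numeric, logical(1))
  body <- df
  for (k in which(num)) body[[k]] <- sprintf("%.10g", df[[k]])
  body[body == "NA"] <- "NA"
  c(sprintf("# epidermabm snapshot iteration=%d config=%s", world$iteration,
            config_hash(world$config)),
    paste(SNAPSHOT_COLUMNS, collapse = "\t"),
    do.call(paste, c(unname(as.list(body)), sep = "\t")))
}

#' Write / read a world snapshot
#'
#' One tab-delimited table per iteration with a fixed, documented column
#' order: `agent_id, agent_kind, subtype, x, y, z, ECM_value, R1, R2, LRCP,
#' LRCE, R1E, R2E, ligand, PRO, mRNA, latent_store_total`. Cells carry their
#' subcellular concentrations; tiles carry `ECM_value` and their latent
#' store; the single physical-solver agent appears as one `solver` row so
#' that the row count equals the model's total agent count. The first line
#' is a `#` comment with the iteration and the configuration hash.
#'
#' @param world An `epi_world`.
#' @param path File to write / read.
#' @return `write_snapshot`: `path`, invisibly. `read_snapshot`: the snapshot
#'   as a data.frame.
#' @export
write_snapshot <- function(world, path) {
  writeLines(snapshot_lines(world), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!identical(names(df), SNAPSHOT_COLUMNS)) {
    stop("read_snapshot(): unexpected column set in ", path)
  }
  df
}
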