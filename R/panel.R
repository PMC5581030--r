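#' Read a mutation panel from a TSV file
#'
#' The panel file has one row per targeted mutation with columns
#' \code{gene}, \code{protein_change}, \code{cdna_change} and
#' \code{group_id}. Mutant probe ids (\code{mut01..}) and one wild-type
#' probe id per group (\code{wt_<group_id>}) are assigned deterministically
#' in file order.
#'
#' @param path TSV file; defaults to the packaged 39-mutation catalog.
#' @return a \code{\link{MutationPanel}}.
#' @export
readPanel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "panel.tsv", package = "melanochip",
                        mustWork = TRUE)
  e <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "protein_change", "cdna_change", "group_id")
  if (!all(need %in% names(e)))
    stop("panel file must have columns ", paste(need, collapse = ", "))
  ## canonicalize + parse up front so malformed entries fail at load time
  e$cdna_change <- vapply(e$cdna_change, canonicalHgvsC, character(1))
  lab <- lapply(e$protein_change, parseProteinLabel)
  e$aa_ref <- vapply(lab, `[[`, character(1), "aa_ref")
  e$codon_number <- vapply(lab, `[[`, integer(1), "codon_number")
  e$aa_alt <- vapply(lab, `[[`, character(1), "aa_alt")
  e$probe_id <- sprintf("mut%02d", seq_len(nrow(e)))
  gid <- unique(e$group_id)
  groups <- data.frame(
    group_id = gid,
    gene = e$gene[match(gid, e$group_id)],
    wt_probe_id = paste0("wt_", gid),
    stringsAsFactors = FALSE)
  new("MutationPanel", entries = e, groups = groups)
}

#' The packaged default 39-mutation melanoma panel
#'
#' Seven BRAF, twelve NRAS, nine KIT, three GNAQ, two GNA11, four MAP2K1 and
#' two MAP2K2 mutations in eleven locus groups.
#'
#' @return a \code{\link{MutationPanel}} with 39 entries.
#' @export
defaultPanel <- function() readPanel()

#' Lay the panel out on a spot grid
#'
#' Places the four corner markers, then every locus group contiguously
#' (wild-type probe first, then its mutant probes), each probe duplicated on
#' two consecutive spots, filling the grid row-major. The layout is
#' deterministic in the panel and geometry.
#'
#' @param panel a \code{\link{MutationPanel}}.
#' @param grid_rows,grid_cols grid dimensions (default 9 x 12, which holds
#'   the default panel's 104 occupied spots exactly).
#' @param pitch center-to-center spot distance, pixels.
#' @param radius nominal spot radius, pixels.
#' @param margin image-edge to first-spot-center distance, pixels.
#' @return a \code{\link{ChipLayout}}.
#' @export
buildLayout <- function(panel, grid_rows = 9L, grid_cols = 12L,
                        pitch = 20, radius = 6, margin = 20) {
  grid_rows <- as.integer(grid_rows); grid_cols <- as.integer(grid_cols)
  e <- panelEntries(panel); g <- panelGroups(panel)
  n_probes <- nrow(e) + nrow(g)
  capacity <- grid_rows * grid_cols - 4L
  if (2L * n_probes > capacity)
    stop("grid too small: ", 2L * n_probes + 4L, " spots needed, ",
         grid_rows * grid_cols, " available")
  spots <- expand.grid(col = seq_len(grid_cols), row = seq_len(grid_rows))
  spots <- spots[, c("row", "col")]
  spots$spot_index <- seq_len(nrow(spots))
  spots$role <- "empty"
  spots$probe_id <- NA_character_
  spots$group_id <- NA_character_
  corner <- spots$row %in% c(1L, grid_rows) & spots$col %in% c(1L, grid_cols)
  spots$role[corner] <- "marker"
  ## group-contiguous probe order: WT probe then its mutants, duplicated
  probe_seq <- do.call(rbind, c(
    list(data.frame(probe_id = character(0), role = character(0),
                    group_id = character(0), stringsAsFactors = FALSE)),
    lapply(seq_len(nrow(g)), function(i) {
      gi <- g[i, ]
      mu <- e[e$group_id == gi$group_id, ]
      data.frame(probe_id = c(gi$wt_probe_id, mu$probe_id),
                 role = c("wt", rep("mut", nrow(mu))),
                 group_id = gi$group_id, stringsAsFactors = FALSE)
    })))
  slots <- which(!corner)
  idx <- rep(seq_len(nrow(probe_seq)), each = 2L)
  take <- slots[seq_along(idx)]
  spots$role[take] <- probe_seq$role[idx]
  spots$probe_id[take] <- probe_seq$probe_id[idx]
  spots$group_id[take] <- probe_seq$group_id[idx]
  rownames(spots) <- NULL
  new("ChipLayout", grid_rows = grid_rows, grid_cols = grid_cols,
      spots = spots[, c("spot_index", "row", "col", "role", "probe_id",
                        "group_id")],
      pitch = pitch, radius = radius, margin = margin)
}

## Continuous pixel center (0-based, row/col order) of each layout spot.
spotCenters <- function(layout) {
  s <- layoutSpots(layout)
  data.frame(spot_index = s$spot_index,
             y = layout@margin + (s$row - 1L) * layout@pitch,
             x = layout@margin + (s$col - 1L) * layout@pitch)
}

#' Write / read a layout manifest (JSON)
#'
#' The manifest serializes the spot map and geometry so that external
#' quantifiers (or the simulator) can consume the same layout.
#'
#' @param layout a \code{\link{ChipLayout}}.
#' @param path JSON file path.
#' @export
writeLayout <- function(layout, path) {
  obj <- list(geometry = layoutGeometry(layout), spots = layoutSpots(layout))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeLayout
#' @export
readLayout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- obj$geometry
  s <- obj$spots
  s$probe_id <- as.character(s$probe_id)
  s$group_id <- as.character(s$group_id)
  s$spot_index <- as.integer(s$spot_index)
  s$row <- as.integer(s$row); s$col <- as.integer(s$col)
  new("ChipLayout", grid_rows = as.integer(g$grid_rows),
      grid_cols = as.integer(g$grid_cols), spots = s,
      pitch = g$pitch, radius = g$radius, margin = g$margin)
}
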