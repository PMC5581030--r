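#' @import methods
#' @importFrom stats median quantile rnorm rlnorm runif setNames complete.cases
#' @importFrom utils read.delim write.table read.csv head
NULL

PANEL_GENES <- c("BRAF", "NRAS", "KIT", "GNAQ", "GNA11", "MAP2K1", "MAP2K2")

## Genes whose driver mutations are treated as mutually exclusive when a
## sample-level report is assembled; MAP2K1/2 may co-occur with BRAF.
EXCLUSIVE_GENES <- c("BRAF", "NRAS", "KIT", "GNAQ", "GNA11")

#' MutationPanel: the targeted mutation catalog
#'
#' An ordered catalog of targeted somatic mutations, each identified by gene,
#' protein change and HGVS coding change, organised into locus groups. Each
#' group corresponds to one clamped amplicon and carries exactly one
#' wild-type probe next to the mutant-specific probes.
#'
#' @slot entries data.frame with columns \code{gene}, \code{protein_change},
#'   \code{cdna_change}, \code{group_id}, \code{probe_id}, plus the parsed
#'   protein-label fields \code{aa_ref}, \code{codon_number}, \code{aa_alt}.
#' @slot groups data.frame with columns \code{group_id}, \code{gene},
#'   \code{wt_probe_id}.
#' @export
setClass("MutationPanel",
         slots = c(entries = "data.frame", groups = "data.frame"))

setValidity("MutationPanel", function(object) {
  e <- object@entries
  g <- object@groups
  msgs <- character()
  need <- c("gene", "protein_change", "cdna_change", "group_id", "probe_id",
            "aa_ref", "codon_number", "aa_alt")
  if (!all(need %in% names(e)))
    return(paste("entries missing columns:",
                 paste(setdiff(need, names(e)), collapse = ", ")))
  if (!all(e$gene %in% PANEL_GENES))
    msgs <- c(msgs, "entry gene outside the seven panel genes")
  if (anyDuplicated(paste(e$gene, e$cdna_change)))
    msgs <- c(msgs, "(gene, cdna_change) pairs must be unique")
  if (!all(e$group_id %in% g$group_id))
    msgs <- c(msgs, "every entry must belong to a declared group")
  if (anyDuplicated(g$group_id) || anyDuplicated(g$wt_probe_id))
    msgs <- c(msgs, "each group must have exactly one wild-type probe")
  if (anyDuplicated(e$probe_id))
    msgs <- c(msgs, "probe ids must be unique")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn MutationPanel entry table accessor
#' @param panel a \code{MutationPanel}
#' @export
panelEntries <- function(panel) panel@entries

#' @describeIn MutationPanel group table accessor
#' @export
panelGroups <- function(panel) panel@groups

setMethod("show", "MutationPanel", function(object) {
  e <- object@entries
  cat("MutationPanel:", nrow(e), "entries in", nrow(object@groups),
      "locus groups\n")
  print(table(factor(e$gene, levels = PANEL_GENES)))
})

#' ChipLayout: spot-grid geometry of the biochip
#'
#' A rectangular grid of gel spots. Every probe (mutant-specific and
#' wild-type) occupies two spots (duplicate gel drops); four fluorescent
#' marker spots sit in the grid corners and anchor grid location on the
#' acquired image.
#'
#' @slot grid_rows,grid_cols integer grid dimensions.
#' @slot spots data.frame with columns \code{spot_index}, \code{row},
#'   \code{col}, \code{role} (\code{"marker"}, \code{"mut"}, \code{"wt"} or
#'   \code{"empty"}), \code{probe_id} (NA for markers/empties) and
#'   \code{group_id}.
#' @slot pitch spot center-to-center distance in pixels.
#' @slot radius nominal spot radius in pixels.
#' @slot margin distance from image edge to the first spot center, pixels.
#' @export
setClass("ChipLayout",
         slots = c(grid_rows = "integer", grid_cols = "integer",
                   spots = "data.frame", pitch = "numeric",
                   radius = "numeric", margin = "numeric"))

setValidity("ChipLayout", function(object) {
  s <- object@spots
  msgs <- character()
  if (nrow(s) != object@grid_rows * object@grid_cols)
    msgs <- c(msgs, "spot table must cover the full grid")
  if (sum(s$role == "marker") != 4L)
    msgs <- c(msgs, "exactly four marker spots required")
  corners <- s$role[s$row %in% c(1L, object@grid_rows) &
                    s$col %in% c(1L, object@grid_cols)]
  if (!all(corners == "marker"))
    msgs <- c(msgs, "the four markers must sit at the grid corners")
  pr <- s$probe_id[s$role %in% c("mut", "wt")]
  if (length(pr) && !all(table(pr) == 2L))
    msgs <- c(msgs, "every probe must occupy exactly two spots")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn ChipLayout spot table accessor
#' @param layout a \code{ChipLayout}
#' @export
layoutSpots <- function(layout) layout@spots

#' @describeIn ChipLayout geometry accessor (pitch, radius, margin, dims)
#' @export
layoutGeometry <- function(layout)
  list(grid_rows = layout@grid_rows, grid_cols = layout@grid_cols,
       pitch = layout@pitch, radius = layout@radius, margin = layout@margin)

setMethod("show", "ChipLayout", function(object) {
  s <- object@spots
  cat(sprintf("ChipLayout: %d x %d grid, pitch %g px, radius %g px\n",
              object@grid_rows, object@grid_cols, object@pitch,
              object@radius))
  cat(sprintf("  %d mutant, %d wild-type, %d marker, %d empty spots\n",
              sum(s$role == "mut"), sum(s$role == "wt"),
              sum(s$role == "marker"), sum(s$role == "empty")))
})

#' ChipImage: an acquired or rendered 16-bit chip image
#'
#' @slot pixels numeric matrix of pixel counts (0-based row/col pixel
#'   coordinates map to matrix row/col minus one).
#' @slot meta list of acquisition metadata: \code{dark_current} (the camera
#'   dark-current intensity I0), \code{bit_depth}, \code{seed}, plus free-form
#'   provenance fields.
#' @export
setClass("ChipImage", slots = c(pixels = "matrix", meta = "list"))

setValidity("ChipImage", function(object) {
  bd <- object@meta$bit_depth
  if (is.null(bd)) return("meta$bit_depth is required")
  mx <- 2^bd - 1
  if (any(object@pixels < 0 | object@pixels > mx))
    return("pixel values outside bit-depth range")
  TRUE
})

#' @describeIn ChipImage pixel matrix accessor
#' @param image a \code{ChipImage}
#' @export
pixelMatrix <- function(image) image@pixels

#' @describeIn ChipImage metadata accessor
#' @export
imageMeta <- function(image) image@meta

setMethod("show", "ChipImage", function(object) {
  cat(sprintf("ChipImage: %d x %d px, %d-bit, range [%g, %g]\n",
              nrow(object@pixels), ncol(object@pixels),
              object@meta$bit_depth, min(object@pixels),
              max(object@pixels)))
})

#' SampleReport: genotype calls for one sample
#'
#' One call per locus group, plus cross-group consistency warnings and
#' provenance.
#'
#' @slot sample_id character scalar.
#' @slot calls data.frame with one row per group: \code{group_id},
#'   \code{gene}, \code{verdict} (\code{"WT"}, \code{"mutant"} or
#'   \code{"no-call"}), \code{probe_id}, \code{protein_change},
#'   \code{cdna_change}, \code{margin} (J_mut - J_wt), \code{flags}.
#' @slot warnings character vector of cross-group consistency warnings.
#' @slot provenance list (image id, parameters, seeds).
#' @export
setClass("SampleReport",
         slots = c(sample_id = "character", calls = "data.frame",
                   warnings = "character", provenance = "list"))

#' @describeIn SampleReport call table accessor
#' @param report a \code{SampleReport}
#' @export
reportCalls <- function(report) report@calls

#' @describeIn SampleReport consistency warning accessor
#' @export
reportWarnings <- function(report) report@warnings

#' @describeIn SampleReport the called mutations as a call data.frame
#'   (zero rows when the sample is wild type at every group)
#' @export
calledMutations <- function(report) {
  m <- report@calls[report@calls$verdict == "mutant", , drop = FALSE]
  m[, c("gene", "protein_change", "cdna_change", "group_id", "probe_id",
        "margin")]
}

setMethod("show", "SampleReport", function(object) {
  m <- calledMutations(object)
  cat("SampleReport", object@sample_id, "-", nrow(object@calls), "groups;")
  if (nrow(m) == 0) cat(" no mutation called\n")
  else cat(" called:", paste(m$gene, m$protein_change, collapse = ", "), "\n")
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})
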