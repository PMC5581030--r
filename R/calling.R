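#' Background-normalized spot signal J
#'
#' \code{J = (I_m - I0) / (B_m - I0)}: interior intensity over local
#' background, both corrected for the camera dark current. Dimensionless;
#' may exceed 1; invariant under global affine intensity scaling applied to
#' \code{I_m}, \code{B_m} and \code{I0} together.
#'
#' @param I_m interior intensity (mean pixel value over the spot interior).
#' @param B_m local background intensity.
#' @param I0 dark-current intensity.
#' @return numeric J, vectorized; \code{NA} where \code{B_m <= I0} (QC
#'   failure, propagated as an excluded spot).
#' @examples
#' normalizeSignal(1000, 200, 100)  # 9
#' @export
normalizeSignal <- function(I_m, B_m, I0) {
  J <- (I_m - I0) / (B_m - I0)
  J[!is.na(B_m) & B_m <= I0] <- NA_real_
  J
}

#' Aggregate spot quantifications into per-group probe signals
#'
#' Computes J per spot, averages the duplicated spots of each probe
#' (QC-failed duplicates dropped; a probe with no surviving spot is
#' excluded), and normalizes by the within-group maximum.
#'
#' @param quant spot table from \code{\link{quantifyChip}}.
#' @param layout a \code{\link{ChipLayout}}.
#' @param panel a \code{\link{MutationPanel}}.
#' @return data.frame with one row per probe: \code{group_id},
#'   \code{probe_id}, \code{role}, \code{gene}, \code{protein_change},
#'   \code{cdna_change}, \code{J} (duplicate-averaged, NA when excluded),
#'   \code{J_norm}, \code{n_spots} (surviving duplicates), \code{flags}.
#' @export
aggregateGroups <- function(quant, layout, panel) {
  e <- panelEntries(panel); g <- panelGroups(panel)
  q <- quant[quant$role %in% c("mut", "wt"), , drop = FALSE]
  q$J <- normalizeSignal(q$I_m, q$B_m, q$I0)
  bad <- q$qc_flags != "" & vapply(strsplit(q$qc_flags, ","), function(fl)
    any(fl %in% c("off-grid", "saturated", "low-background")), logical(1))
  q$J[bad] <- NA_real_
  probes <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    gi <- g[i, ]
    mu <- e[e$group_id == gi$group_id, ]
    data.frame(group_id = gi$group_id,
               probe_id = c(gi$wt_probe_id, mu$probe_id),
               role = c("wt", rep("mut", nrow(mu))),
               gene = gi$gene,
               protein_change = c(NA_character_, mu$protein_change),
               cdna_change = c(NA_character_, mu$cdna_change),
               stringsAsFactors = FALSE)
  }))
  agg <- vapply(probes$probe_id, function(p) {
    js <- q$J[q$probe_id == p]
    js <- js[!is.na(js)]
    c(J = if (length(js)) mean(js) else NA_real_, n = length(js))
  }, numeric(2))
  probes$J <- agg["J", ]
  probes$n_spots <- as.integer(agg["n", ])
  probes$flags <- ifelse(probes$n_spots == 0L, "probe-excluded",
                         ifelse(probes$n_spots == 1L, "single-duplicate",
                                ""))
  probes$J_norm <- NA_real_
  for (gid in g$group_id) {
    sel <- probes$group_id == gid
    mx <- suppressWarnings(max(probes$J[sel], na.rm = TRUE))
    if (is.finite(mx) && mx > 0)
      probes$J_norm[sel] <- probes$J[sel] / mx
  }
  rownames(probes) <- NULL
  probes
}

#' Apply the mutation-calling rule to one locus group
#'
#' A mutant probe qualifies when its duplicate-averaged signal exceeds the
#' group's wild-type probe (\code{J_mut > J_wt}) and clears the
#' signal-to-background criterion \code{J_mut >= min_sbr} (i.e. the
#' dark-corrected spot signal is at least \code{min_sbr} times the
#' dark-corrected background). Among qualifying probes the one with maximal
#' J is called; an exact tie yields a no-call with an ambiguity flag; with
#' no qualifier the group is wild type.
#'
#' @param group_signal rows of an \code{\link{aggregateGroups}} table for
#'   one group.
#' @param min_sbr signal-to-background threshold (default 2).
#' @return one-row data.frame: \code{group_id}, \code{gene}, \code{verdict}
#'   (\code{"WT"}, \code{"mutant"}, \code{"no-call"}), \code{probe_id},
#'   \code{protein_change}, \code{cdna_change}, \code{margin}
#'   (\code{max J_mut - J_wt}), \code{flags}.
#' @export
callGroup <- function(group_signal, min_sbr = 2) {
  gs <- group_signal
  stopifnot(length(unique(gs$group_id)) == 1L)
  out <- data.frame(group_id = gs$group_id[1], gene = gs$gene[1],
                    verdict = "no-call", probe_id = NA_character_,
                    protein_change = NA_character_,
                    cdna_change = NA_character_, margin = NA_real_,
                    flags = "", stringsAsFactors = FALSE)
  wt <- gs[gs$role == "wt", ]
  if (nrow(wt) != 1L || is.na(wt$J)) {
    out$flags <- "wt-missing"
    return(out)
  }
  mut <- gs[gs$role == "mut" & !is.na(gs$J), , drop = FALSE]
  if (nrow(mut)) out$margin <- max(mut$J) - wt$J
  qual <- mut[mut$J > wt$J & mut$J >= min_sbr, , drop = FALSE]
  if (nrow(qual) == 0L) {
    out$verdict <- "WT"
    return(out)
  }
  top <- qual[qual$J == max(qual$J), , drop = FALSE]
  if (nrow(top) > 1L) {
    out$flags <- "ambiguous-tie"
    return(out)
  }
  out$verdict <- "mutant"
  out$probe_id <- top$probe_id
  out$protein_change <- top$protein_change
  out$cdna_change <- top$cdna_change
  out$margin <- top$J - wt$J
  out
}

#' Assemble the per-sample genotype report
#'
#' Calls every locus group and records a mutual-exclusivity warning (never
#' an error) when two of BRAF/NRAS/KIT/GNAQ/GNA11 carry mutations in one
#' sample; MAP2K1/2 co-occurring with BRAF is expected and not warned.
#'
#' @param group_signals table from \code{\link{aggregateGroups}}.
#' @param panel a \code{\link{MutationPanel}}.
#' @param sample_id sample identifier.
#' @param min_sbr signal-to-background threshold.
#' @param provenance list carried into the report (image id, seeds, ...).
#' @return a \code{\link{SampleReport}}.
#' @export
callSample <- function(group_signals, panel, sample_id = "sample",
                       min_sbr = 2, provenance = list()) {
  g <- panelGroups(panel)
  calls <- do.call(rbind, lapply(g$group_id, function(gid)
    callGroup(group_signals[group_signals$group_id == gid, , drop = FALSE],
              min_sbr = min_sbr)))
  warnings <- character(0)
  mut_genes <- unique(calls$gene[calls$verdict == "mutant"])
  ex <- intersect(mut_genes, EXCLUSIVE_GENES)
  if (length(ex) > 1L)
    warnings <- paste0("mutual-exclusivity: mutations called in ",
                       paste(sort(ex), collapse = " and "))
  provenance$min_sbr <- min_sbr
  new("SampleReport", sample_id = sample_id, calls = calls,
      warnings = warnings, provenance = provenance)
}

#' Quantify and call one chip image end to end
#'
#' Convenience wrapper: locate grid, quantify spots, aggregate groups and
#' call the sample.
#'
#' @inheritParams callSample
#' @param image a \code{\link{ChipImage}}.
#' @param layout a \code{\link{ChipLayout}}.
#' @export
callChip <- function(image, layout, panel, sample_id = NULL, min_sbr = 2) {
  if (is.null(sample_id))
    sample_id <- imageMeta(image)$sample_id %||% "sample"
  quant <- quantifyChip(image, layout)
  gs <- aggregateGroups(quant, layout, panel)
  callSample(gs, panel, sample_id = sample_id, min_sbr = min_sbr,
             provenance = list(image_id = sample_id,
                               spot_seed = imageMeta(image)$spot_seed,
                               pixel_seed = imageMeta(image)$pixel_seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate the limit of detection from a dilution series
#'
#' The LoD is the smallest mutant fraction at which the spiked mutation is
#' called in all replicates (\code{policy = "all"}; \code{"majority"}
#' selectable), subject to the specificity constraint that every
#' zero-fraction replicate is wild type - any false call at 0\% makes the
#' LoD undefined and raises an error.
#'
#' @param reports list of \code{\link{SampleReport}}s.
#' @param truths list of truth manifests (elements \code{fraction},
#'   \code{probe_id}, as produced by \code{\link{generateDilutionSeries}}),
#'   parallel to \code{reports}.
#' @param panel a \code{\link{MutationPanel}}.
#' @param policy \code{"all"} or \code{"majority"}.
#' @return list: \code{lod} (fraction, or \code{NA}), \code{status}
#'   (\code{"ok"} or \code{"above-range"}), \code{detection} (per-fraction
#'   detected/replicate counts).
#' @export
estimateLod <- function(reports, truths, panel = defaultPanel(),
                        policy = c("all", "majority")) {
  policy <- match.arg(policy)
  stopifnot(length(reports) == length(truths))
  frac <- vapply(truths, `[[`, numeric(1), "fraction")
  if (length(unique(frac)) < 2L)
    stop("a dilution series needs at least two distinct fractions")
  e <- panelEntries(panel)
  detected <- vapply(seq_along(reports), function(i) {
    calls <- reportCalls(reports[[i]])
    if (frac[i] == 0)
      return(all(calls$verdict %in% c("WT", "no-call")) &&
               !any(calls$verdict == "mutant"))
    pid <- truths[[i]]$probe_id
    gid <- e$group_id[e$probe_id == pid]
    any(calls$verdict == "mutant" & calls$probe_id == pid &
          calls$group_id == gid)
  }, logical(1))
  if (any(frac == 0)) {
    zero_ok <- detected[frac == 0]
    if (!all(zero_ok))
      stop("LoD undefined: ", sum(!zero_ok),
           " zero-fraction replicate(s) produced a false mutant call")
  }
  det <- data.frame(fraction = sort(unique(frac)))
  det$n_replicates <- vapply(det$fraction, function(f) sum(frac == f),
                             integer(1))
  det$n_detected <- vapply(det$fraction, function(f)
    sum(detected[frac == f] & frac[frac == f] > 0), integer(1))
  nz <- det[det$fraction > 0, ]
  pass <- if (policy == "all") nz$n_detected == nz$n_replicates
          else nz$n_detected > nz$n_replicates / 2
  if (!any(pass))
    return(list(lod = NA_real_, status = "above-range", detection = det,
                policy = policy))
  list(lod = min(nz$fraction[pass]), status = "ok", detection = det,
       policy = policy)
}

#' Write a sample report to JSON / flat TSV
#'
#' @param report a \code{\link{SampleReport}}.
#' @param path output path (JSON; a sibling \code{.tsv} is written with the
#'   flat call table).
#' @export
writeSampleReport <- function(report, path) {
  obj <- list(sample_id = report@sample_id, calls = report@calls,
              warnings = report@warnings, provenance = report@provenance,
              tool = paste0("melanochip ",
                            as.character(utils::packageVersion("melanochip"))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  tsv <- sub("\\.json$", ".tsv", path)
  if (tsv == path) tsv <- paste0(path, ".tsv")
  flat <- cbind(sample = report@sample_id, report@calls)
  write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
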