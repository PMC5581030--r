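#' Ground truth for one simulated sample
#'
#' @param genotype character vector of mutant probe ids carried by the
#'   sample (character(0) = wild type), referring to panel entries.
#' @param mutant_fraction proportion of template DNA carrying the mutant
#'   allele, in [0, 1].
#' @param dna_input template copy number entering the clamped PCR.
#' @return list of class \code{sample_truth}.
#' @export
sampleTruth <- function(genotype = character(0), mutant_fraction = 0,
                        dna_input = 1e4) {
  stopifnot(mutant_fraction >= 0, mutant_fraction <= 1, dna_input >= 0)
  if (mutant_fraction > 0 && length(genotype) == 0L)
    stop("nonzero mutant_fraction requires a genotype")
  if (mutant_fraction == 0 && length(genotype) > 0L)
    stop("empty mutant_fraction requires an empty genotype")
  structure(list(genotype = genotype, mutant_fraction = mutant_fraction,
                 dna_input = dna_input), class = "sample_truth")
}

#' Clamped-PCR kinetics parameters
#'
#' The LNA clamp anneals to the wild-type sequence and blocks its extension,
#' so the wild-type allele amplifies with a much lower per-cycle efficiency
#' than the mutant allele. Amplification is modelled as capped geometric
#' growth with allele-specific efficiencies.
#'
#' @param cycles number of PCR cycles.
#' @param eff_mut per-cycle amplification efficiency of the mutant template,
#'   in (0, 1].
#' @param eff_wt_clamped per-cycle efficiency of the clamped wild-type
#'   template, in [0, 1), strictly below \code{eff_mut}.
#' @param saturation_cap maximum product copies per allele.
#' @export
clampParams <- function(cycles = 35L, eff_mut = 0.9, eff_wt_clamped = 0.2,
                        saturation_cap = 1e12) {
  stopifnot(cycles >= 1, eff_mut > 0, eff_mut <= 1, eff_wt_clamped >= 0,
            eff_wt_clamped < eff_mut, saturation_cap > 0)
  structure(list(cycles = as.integer(cycles), eff_mut = eff_mut,
                 eff_wt_clamped = eff_wt_clamped,
                 saturation_cap = saturation_cap), class = "clamp_params")
}

#' Simulate LNA-clamped multiplex PCR product amounts
#'
#' Closed form per locus group: the group carrying a genotype entry yields
#' \code{min(cap, f * N0 * (1 + eff_mut)^cycles)} mutant copies and
#' \code{min(cap, (1 - f) * N0 * (1 + eff_wt_clamped)^cycles)} clamped
#' wild-type copies. Groups whose locus is wild type in the sample see the
#' full template as wild type (mutant copies 0). Deterministic.
#'
#' @param truth a \code{\link{sampleTruth}}.
#' @param panel a \code{\link{MutationPanel}}.
#' @param params a \code{\link{clampParams}}.
#' @return data.frame with columns \code{group_id}, \code{allele} (a mutant
#'   probe id or \code{"WT"}), \code{copies}.
#' @export
simulateClampPcr <- function(truth, panel, params = clampParams()) {
  stopifnot(inherits(truth, "sample_truth"), inherits(params, "clamp_params"))
  e <- panelEntries(panel); g <- panelGroups(panel)
  if (!all(truth$genotype %in% e$probe_id))
    stop("genotype probe ids not in panel: ",
         paste(setdiff(truth$genotype, e$probe_id), collapse = ", "))
  f <- truth$mutant_fraction; n0 <- truth$dna_input
  grow <- function(copies, eff)
    pmin(params$saturation_cap, copies * (1 + eff)^params$cycles)
  out <- lapply(g$group_id, function(gid) {
    muts <- truth$genotype[e$group_id[match(truth$genotype, e$probe_id)] ==
                             gid]
    wt_frac <- if (length(muts)) 1 - f else 1
    rows <- data.frame(group_id = gid, allele = "WT",
                       copies = grow(wt_frac * n0, params$eff_wt_clamped),
                       stringsAsFactors = FALSE)
    if (length(muts))
      rows <- rbind(rows,
                    data.frame(group_id = gid, allele = muts,
                               copies = grow(f * n0, params$eff_mut),
                               stringsAsFactors = FALSE))
    rows
  })
  do.call(rbind, out)
}

#' Hybridization forward-model parameters
#'
#' Each probe's noiseless fluorescence above background is
#' \code{gain * sum_allele w(probe, allele) * copies(allele)}, where the
#' cross-hybridization weight \code{w} is 1 for the probe's own allele,
#' \code{crosshyb} for any other allele of the same locus group and 0 across
#' groups. Nested second-round PCR and Cy5-dUTP label incorporation are
#' absorbed into \code{gain}. Spot-to-spot noise is multiplicative
#' log-normal on the hybridization component (probe-density variation);
#' duplicated spots receive independent draws.
#'
#' @param gain fluorescence counts per product copy.
#' @param crosshyb within-group cross-hybridization weight in [0, 1).
#' @param background_mean mean optical background B (counts), includes dark
#'   current.
#' @param dark_current camera dark-current intensity I0 (counts),
#'   \code{< background_mean}.
#' @param cv coefficient of variation of the multiplicative spot noise.
#' @param marker_value fixed brightness of the corner marker spots.
#' @export
hybParams <- function(gain = 2e-9, crosshyb = 0.05, background_mean = 500,
                      dark_current = 100, cv = 0.10,
                      marker_value = 30000) {
  stopifnot(gain > 0, crosshyb >= 0, crosshyb < 1,
            background_mean > dark_current, dark_current >= 0, cv >= 0)
  structure(list(gain = gain, crosshyb = crosshyb,
                 background_mean = background_mean,
                 dark_current = dark_current, cv = cv,
                 marker_value = marker_value), class = "hyb_params")
}

#' Simulate per-spot intensities from PCR products
#'
#' @param products product table from \code{\link{simulateClampPcr}}.
#' @param layout a \code{\link{ChipLayout}}.
#' @param params a \code{\link{hybParams}}.
#' @param seed RNG seed for the spot-noise draws; required whenever
#'   \code{params$cv > 0} (reproducibility contract).
#' @return list with \code{noiseless} and \code{noisy} spot tables
#'   (\code{spot_index}, \code{probe_id}, \code{role}, \code{value}) and the
#'   \code{seed} used (NA for noise-free simulations).
#' @export
simulateSpotTruth <- function(products, layout, params = hybParams(),
                              seed = NULL) {
  stopifnot(inherits(params, "hyb_params"))
  if (params$cv > 0 && is.null(seed))
    stop("a seed is required when spot noise is requested")
  s <- layoutSpots(layout)
  ## noiseless probe-level signal above background
  probe_sig <- function(probe_id, role, group_id) {
    if (role %in% c("marker", "empty"))
      return(if (role == "marker") params$marker_value - params$background_mean
             else 0)
    pg <- products[products$group_id == group_id, , drop = FALSE]
    own <- if (role == "wt") "WT" else probe_id
    w <- ifelse(pg$allele == own, 1, params$crosshyb)
    params$gain * sum(w * pg$copies)
  }
  sig <- vapply(seq_len(nrow(s)), function(i)
    probe_sig(s$probe_id[i], s$role[i], s$group_id[i]), numeric(1))
  noiseless <- data.frame(spot_index = s$spot_index, probe_id = s$probe_id,
                          role = s$role,
                          value = params$background_mean + sig,
                          stringsAsFactors = FALSE)
  noisy <- noiseless
  used_seed <- NA_integer_
  if (params$cv > 0) {
    used_seed <- as.integer(seed)
    set.seed(used_seed)
    sdlog <- sqrt(log(1 + params$cv^2))
    eps <- rlnorm(nrow(s), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    noisy$value <- params$background_mean + eps * sig
  }
  structure(list(noiseless = noiseless, noisy = noisy, seed = used_seed,
                 background_mean = params$background_mean,
                 dark_current = params$dark_current),
            class = "spot_truth")
}

#' Image-rendering parameters
#'
#' @param bit_depth image bit depth (16).
#' @param edge spot edge softness in pixels (linear intensity roll-off
#'   across \code{radius - edge/2 .. radius + edge/2}); the interior used
#'   for quantification stays at full assigned intensity.
#' @param pixel_sd additive Gaussian pixel-noise standard deviation, counts.
#' @param seed RNG seed for pixel noise; required when \code{pixel_sd > 0}.
#' @export
imageParams <- function(bit_depth = 16L, edge = 1, pixel_sd = 3,
                        seed = NULL) {
  stopifnot(bit_depth %in% c(8L, 16L), edge >= 0, pixel_sd >= 0)
  structure(list(bit_depth = as.integer(bit_depth), edge = edge,
                 pixel_sd = pixel_sd, seed = seed), class = "image_params")
}

#' Render a chip image from per-spot intensities
#'
#' Draws each spot as a soft-edged disk whose interior equals the assigned
#' intensity before pixel noise; background pixels sit at the background
#' mean. Values are rounded to integer counts and clipped to the bit depth
#' (with a warning when clipping occurs).
#'
#' @param spots a spot table (\code{spot_index}, \code{value}) - typically
#'   the \code{noisy} element of \code{\link{simulateSpotTruth}} - or a
#'   \code{spot_truth} object (its noisy realization is rendered).
#' @param layout a \code{\link{ChipLayout}}.
#' @param params an \code{\link{imageParams}}.
#' @param background_mean,dark_current image background / camera dark
#'   current; defaulted from the \code{spot_truth} when available.
#' @return a \code{\link{ChipImage}} whose metadata records the dark
#'   current, seeds and rendering parameters.
#' @export
renderChipImage <- function(spots, layout, params = imageParams(),
                            background_mean = NULL, dark_current = NULL) {
  stopifnot(inherits(params, "image_params"))
  spot_seed <- NA_integer_
  if (inherits(spots, "spot_truth")) {
    if (is.null(background_mean)) background_mean <- spots$background_mean
    if (is.null(dark_current)) dark_current <- spots$dark_current
    spot_seed <- spots$seed
    spots <- spots$noisy
  }
  if (is.null(background_mean) || is.null(dark_current))
    stop("background_mean and dark_current are required")
  if (params$pixel_sd > 0 && is.null(params$seed))
    stop("a seed is required when pixel noise is requested")
  ctr <- spotCenters(layout)
  ny <- 2 * layout@margin + (layout@grid_rows - 1) * layout@pitch + 1
  nx <- 2 * layout@margin + (layout@grid_cols - 1) * layout@pitch + 1
  img <- matrix(background_mean, nrow = ny, ncol = nx)
  R <- layout@radius; e <- params$edge
  win <- ceiling(R + e / 2)
  spots <- merge(spots, ctr, by = "spot_index")
  for (i in seq_len(nrow(spots))) {
    if (spots$value[i] == background_mean) next
    cy <- spots$y[i]; cx <- spots$x[i]
    ys <- max(0, floor(cy - win)):min(ny - 1, ceiling(cy + win))
    xs <- max(0, floor(cx - win)):min(nx - 1, ceiling(cx + win))
    d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
    w <- pmin(1, pmax(0, if (e > 0) (R + e / 2 - d) / e else (d <= R) * 1))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
      w * (spots$value[i] - background_mean)
  }
  if (params$pixel_sd > 0) {
    set.seed(as.integer(params$seed))
    img <- img + rnorm(length(img), sd = params$pixel_sd)
  }
  img <- round(img)
  mx <- 2^params$bit_depth - 1
  if (any(img > mx))
    warning(sum(img > mx), " pixel(s) clipped to the bit-depth maximum")
  img[img > mx] <- mx
  img[img < 0] <- 0
  new("ChipImage", pixels = img,
      meta = list(dark_current = dark_current,
                  background_mean = background_mean,
                  bit_depth = params$bit_depth,
                  spot_seed = spot_seed,
                  pixel_seed = if (params$pixel_sd > 0)
                    as.integer(params$seed) else NA_integer_))
}

#' Write / read a 16-bit grayscale chip image (TIFF)
#'
#' Metadata (dark current, seeds) travels in a JSON sidecar
#' \code{<path>.json} written and read alongside the TIFF.
#'
#' @param image a \code{\link{ChipImage}}.
#' @param path TIFF file path.
#' @export
writeChipImage <- function(image, path) {
  mx <- 2^image@meta$bit_depth - 1
  tiff::writeTIFF(image@pixels / mx, path, bits.per.sample = 16L)
  jsonlite::write_json(image@meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeChipImage
#' @export
readChipImage <- function(path) {
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(bit_depth = 16L)
  if (is.null(meta$bit_depth)) meta$bit_depth <- 16L
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  new("ChipImage", pixels = round(px * (2^meta$bit_depth - 1)), meta = meta)
}

## Deterministic per-replicate sub-seeds below 2^31.
deriveSeeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(2147483646L, n)
}

#' Default dilution fractions of the sensitivity series
#'
#' Mutant DNA diluted into wild-type DNA at 0, 0.25, 0.5, 1, 5, 10, 50 and
#' 100 percent.
#' @export
dilutionFractions <- function()
  c(0, 0.0025, 0.005, 0.01, 0.05, 0.10, 0.50, 1)

#' Generate a ground-truthed dilution series of chip images
#'
#' Simulates the sensitivity experiment: one mutation serially diluted into
#' wild-type DNA, each fraction in replicate, each replicate taken through
#' clamped PCR, hybridization and image rendering. Per-replicate seeds are
#' derived deterministically from the master seed.
#'
#' @param probe_id mutant probe id to spike (default: the panel's BRAF
#'   V600E c.1799T>A entry).
#' @param panel,layout panel and layout (defaults built from the packaged
#'   panel).
#' @param fractions mutant fractions; default \code{\link{dilutionFractions}}.
#' @param replicates replicates per fraction (default 3).
#' @param seed master seed.
#' @param clamp,hyb,image forward-model parameter objects.
#' @return list of chips; each element holds \code{image} (a
#'   \code{\link{ChipImage}}) and \code{truth} (sample id, probe id,
#'   fraction, replicate, seeds).
#' @export
generateDilutionSeries <- function(probe_id = NULL, panel = defaultPanel(),
                                   layout = buildLayout(panel),
                                   fractions = dilutionFractions(),
                                   replicates = 3L, seed = 1L,
                                   clamp = clampParams(),
                                   hyb = hybParams(),
                                   image = imageParams()) {
  stopifnot(all(fractions >= 0 & fractions <= 1), replicates >= 1)
  e <- panelEntries(panel)
  if (is.null(probe_id))
    probe_id <- e$probe_id[e$gene == "BRAF" & e$cdna_change == "c.1799T>A"]
  stopifnot(probe_id %in% e$probe_id)
  grid <- expand.grid(replicate = seq_len(replicates), fraction = fractions)
  seeds <- deriveSeeds(seed, 2L * nrow(grid))
  lapply(seq_len(nrow(grid)), function(i) {
    f <- grid$fraction[i]
    truth <- sampleTruth(genotype = if (f > 0) probe_id else character(0),
                         mutant_fraction = f)
    prods <- simulateClampPcr(truth, panel, clamp)
    st <- simulateSpotTruth(prods, layout, hyb, seed = seeds[2L * i - 1L])
    ip <- image; ip$seed <- seeds[2L * i]
    img <- renderChipImage(st, layout, ip)
    sid <- sprintf("dil_f%g_r%d", f * 100, grid$replicate[i])
    img@meta$sample_id <- sid
    list(image = img,
         truth = list(sample_id = sid, probe_id = probe_id, fraction = f,
                      replicate = grid$replicate[i],
                      spot_seed = st$seed, pixel_seed = ip$seed,
                      master_seed = as.integer(seed)))
  })
}

#' Generate a synthetic patient cohort with per-method calls
#'
#' Samples per-patient genotypes from per-variant frequencies (default: the
#' packaged biochip cohort frequencies), treating BRAF, NRAS, KIT, GNAQ and
#' GNA11 as mutually exclusive drivers and allowing MAP2K1/2 to co-occur
#' with BRAF. Observed method calls are the true genotype thinned by a
#' per-method dropout (false-negative) probability. Clinical covariates are
#' drawn from a simple cohort model (sex ~ Bernoulli, age ~ Normal(53.7,
#' 16.4), subtype categorical).
#'
#' @param n cohort size.
#' @param variant_freqs data.frame \code{gene}, \code{protein_change},
#'   \code{cdna_change}, \code{freq} (per-variant probabilities; exclusive
#'   genes must sum to <= 1). Default: packaged biochip counts / 253.
#' @param method_dropout named numeric vector of per-method false-negative
#'   probabilities, e.g. \code{c(biochip = 0, sanger = 0.3)}.
#' @param seed RNG seed.
#' @return cohort data.frame (one row per sample) with true and observed
#'   call-string columns and covariates, readable by the cohort operations.
#' @export
generateCohort <- function(n, variant_freqs = NULL,
                           method_dropout = c(biochip = 0), seed = 1L) {
  stopifnot(n >= 0)
  if (is.null(variant_freqs)) {
    vf <- read.delim(system.file("extdata", "cohort_variant_counts.tsv",
                                 package = "melanochip", mustWork = TRUE),
                     stringsAsFactors = FALSE)
    variant_freqs <- data.frame(vf[, c("gene", "protein_change",
                                       "cdna_change")],
                                freq = vf$n_biochip / 253,
                                stringsAsFactors = FALSE)
  }
  excl <- variant_freqs[variant_freqs$gene %in% EXCLUSIVE_GENES, ]
  co <- variant_freqs[!variant_freqs$gene %in% EXCLUSIVE_GENES, ]
  if (sum(excl$freq) > 1)
    stop("exclusive-gene variant frequencies sum above 1")
  cols <- c("true_calls", names(method_dropout))
  if (n == 0L) {
    out <- data.frame(sample_id = character(0))
    for (cl in c(cols, "sex", "age", "subtype")) out[[cl]] <- character(0)
    return(out)
  }
  set.seed(as.integer(seed))
  tok <- function(i, tab) paste(tab$gene[i], tab$protein_change[i],
                                tab$cdna_change[i], sep = ":")
  ## one exclusive driver (or WT) per sample
  drv <- sample.int(nrow(excl) + 1L, n, replace = TRUE,
                    prob = c(excl$freq, 1 - sum(excl$freq)))
  calls <- ifelse(drv <= nrow(excl), tok(drv, excl), "")
  ## co-occurring MAP2K1/2 variants ride on BRAF carriers
  braf <- excl$gene[pmin(drv, nrow(excl))] == "BRAF" & drv <= nrow(excl)
  p_braf <- sum(excl$freq[excl$gene == "BRAF"])
  for (j in seq_len(nrow(co))) {
    if (co$freq[j] <= 0) next
    hit <- braf & runif(n) < co$freq[j] / p_braf
    calls[hit] <- paste(calls[hit], tok(j, co), sep = ";")
  }
  truth <- ifelse(calls == "", "WT", sub("^;", "", calls))
  out <- data.frame(sample_id = sprintf("sim%04d", seq_len(n)),
                    is_cell_line = FALSE, true_calls = truth,
                    stringsAsFactors = FALSE)
  for (m in names(method_dropout)) {
    obs <- vapply(truth, function(tc) {
      if (tc == "WT") return("WT")
      kept <- Filter(function(x) runif(1) >= method_dropout[[m]],
                     strsplit(tc, ";", fixed = TRUE)[[1]])
      if (length(kept)) paste(kept, collapse = ";") else "WT"
    }, character(1), USE.NAMES = FALSE)
    out[[m]] <- obs
  }
  out$sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(140, 97))
  out$age <- round(pmax(0, rnorm(n, 53.7, 16.4)), 1)
  out$subtype <- sample(c("nodular", "superficial", "lentigo", "acral", NA),
                        n, replace = TRUE, prob = c(43, 24, 10, 1, 175))
  out
}
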