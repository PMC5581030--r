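panel <- defaultPanel()
layout <- buildLayout(panel)

test_that("J normalization is the dark-corrected background ratio", {
  expect_equal(normalizeSignal(1000, 200, 100), 9)
  expect_equal(normalizeSignal(100, 500, 100), 0)   # I_m = I0
  expect_true(is.na(normalizeSignal(1000, 90, 100)))  # B_m <= I0 fails QC
  set.seed(4)
  for (i in 1:50) {
    i0 <- runif(1, 0, 200); b <- i0 + runif(1, 1, 500)
    im <- runif(1, 0, 5000)
    expect_equal(normalizeSignal(im, b, i0), (im - i0) / (b - i0))
  }
})

test_that("duplicate averaging and within-group max normalization", {
  quant <- data.frame(
    spot_index = 1:6,
    probe_id = c("wt_BRAF_600", "wt_BRAF_600", "mut01", "mut01",
                 "mut02", "mut02"),
    role = c("wt", "wt", "mut", "mut", "mut", "mut"),
    group_id = "BRAF_600",
    I_m = c(300, 300, 500, 700, 200, 150), B_m = 200, I0 = 100,
    qc_flags = c("", "", "", "", "", "low-background"),
    stringsAsFactors = FALSE)
  gs <- aggregateGroups(quant, layout, panel)
  b <- gs[gs$group_id == "BRAF_600", ]
  expect_equal(b$J[b$probe_id == "wt_BRAF_600"], 2)       # mean(2, 2)
  expect_equal(b$J[b$probe_id == "mut01"], 5)             # mean(4, 6)
  # QC-failed duplicate dropped: probe J equals the survivor
  expect_equal(b$J[b$probe_id == "mut02"], 1)
  expect_equal(b$flags[b$probe_id == "mut02"], "single-duplicate")
  expect_equal(b$J_norm[b$probe_id == "mut01"], 1)
  expect_equal(b$J_norm[b$probe_id == "wt_BRAF_600"], 2 / 5)
  # probes with no surviving spots are excluded
  expect_true(all(is.na(b$J[!b$probe_id %in%
                              c("wt_BRAF_600", "mut01", "mut02")])))
})

test_that("the calling rule matches a brute-force oracle on an exhaustive grid", {
  vals <- c(NA, 0.5, 1, 1.9, 2, 2.1, 3)
  grid <- expand.grid(wt = vals, m1 = vals, m2 = vals)
  for (i in seq_len(nrow(grid))) {
    gs <- makeGroupSignal(grid$wt[i], c(grid$m1[i], grid$m2[i]))
    gs$flags[is.na(gs$J)] <- "probe-excluded"
    call <- callGroup(gs, min_sbr = 2)
    oracle <- bruteCallOracle(grid$wt[i], c(grid$m1[i], grid$m2[i]))
    expect_equal(call$verdict, oracle$verdict,
                 info = paste(grid[i, ], collapse = "/"))
    if (oracle$verdict == "mutant")
      expect_equal(call$probe_id, paste0("m", oracle$which))
  }
})

test_that("calling rule details: margin, signal-to-background, ties", {
  # J_mut > J_wt with strong signal-to-background: mutant called
  g <- makeGroupSignal(1.5, c(5, 1.2))
  call <- callGroup(g)
  expect_equal(call$verdict, "mutant")
  expect_equal(call$margin, 3.5)
  # J_mut > J_wt but below min_sbr: wild type
  expect_equal(callGroup(makeGroupSignal(1.0, 1.5))$verdict, "WT")
  # threshold is exposed
  expect_equal(callGroup(makeGroupSignal(1.0, 1.5), min_sbr = 1.4)$verdict,
               "mutant")
  # exact tie between qualifying probes: ambiguous no-call
  tie <- callGroup(makeGroupSignal(1.0, c(4, 4)))
  expect_equal(tie$verdict, "no-call")
  expect_match(tie$flags, "ambiguous")
  # missing wild-type probe: no-call
  nw <- makeGroupSignal(NA, c(4, 1))
  expect_equal(callGroup(nw)$verdict, "no-call")
  expect_match(callGroup(nw)$flags, "wt-missing")
})

test_that("sample assembly warns on exclusivity but tolerates BRAF+MAP2K1", {
  mkgs <- function(mut_probes) {
    gs <- aggregateGroups(
      quantifyChip(noiselessChip(fraction = 0)$image, layout), layout,
      panel)
    for (p in mut_probes) {
      gs$J[gs$probe_id == p] <- 6
    }
    gs
  }
  e <- panelEntries(panel)
  braf <- e$probe_id[e$gene == "BRAF" & e$cdna_change == "c.1799T>A"]
  map2k1 <- e$probe_id[e$gene == "MAP2K1" & e$cdna_change == "c.370C>T"]
  nras <- e$probe_id[e$gene == "NRAS" & e$cdna_change == "c.181C>A"]
  ok <- callSample(mkgs(c(braf, map2k1)), panel, "s1")
  expect_length(reportWarnings(ok), 0L)
  expect_setequal(calledMutations(ok)$gene, c("BRAF", "MAP2K1"))
  bad <- callSample(mkgs(c(braf, nras)), panel, "s2")
  expect_match(reportWarnings(bad), "mutual-exclusivity")
  wt <- callSample(mkgs(character(0)), panel, "s3")
  expect_equal(nrow(reportCalls(wt)), 11L)
  expect_true(all(reportCalls(wt)$verdict == "WT"))
})

test_that("J values and calls are invariant under global intensity scaling", {
  chip <- noiselessChip(fraction = 0.01)
  g <- 1.7
  img2 <- new("ChipImage", pixels = round(pixelMatrix(chip$image) * g),
              meta = modifyList(imageMeta(chip$image),
                                list(dark_current =
                                       imageMeta(chip$image)$dark_current * g)))
  gs1 <- aggregateGroups(quantifyChip(chip$image, layout), layout, panel)
  gs2 <- aggregateGroups(quantifyChip(img2, layout), layout, panel)
  expect_equal(gs2$J, gs1$J, tolerance = 0.01)
  r1 <- callSample(gs1, panel, "a")
  r2 <- callSample(gs2, panel, "b")
  expect_equal(reportCalls(r2)$verdict, reportCalls(r1)$verdict)
  expect_equal(reportCalls(r2)$probe_id, reportCalls(r1)$probe_id)
})

test_that("LoD logic: detection policies, range overflow and 0% specificity", {
  mkreport <- function(probe_id, called) {
    calls <- data.frame(group_id = panelGroups(panel)$group_id,
                        gene = panelGroups(panel)$gene, verdict = "WT",
                        probe_id = NA_character_,
                        protein_change = NA_character_,
                        cdna_change = NA_character_, margin = NA_real_,
                        flags = "", stringsAsFactors = FALSE)
    if (called) {
      e <- panelEntries(panel)
      gid <- e$group_id[e$probe_id == probe_id]
      calls$verdict[calls$group_id == gid] <- "mutant"
      calls$probe_id[calls$group_id == gid] <- probe_id
    }
    new("SampleReport", sample_id = "x", calls = calls,
        warnings = character(0), provenance = list())
  }
  series <- function(pattern) {
    # pattern: named vector fraction -> detected count out of 3
    fr <- rep(as.numeric(names(pattern)), each = 3)
    det <- unlist(lapply(pattern, function(k) c(rep(TRUE, k),
                                                rep(FALSE, 3 - k))))
    list(reports = mapply(function(f, d) mkreport("mut01", f > 0 & d),
                          fr, det, SIMPLIFY = FALSE),
         truths = lapply(fr, function(f) list(fraction = f,
                                              probe_id = "mut01")))
  }
  s <- series(c("0" = 0, "0.0025" = 1, "0.005" = 3, "0.01" = 3))
  expect_equal(estimateLod(s$reports, s$truths, panel)$lod, 0.005)
  expect_equal(estimateLod(s$reports, s$truths, panel,
                           policy = "majority")$lod, 0.005)
  s2 <- series(c("0" = 0, "0.0025" = 3, "0.005" = 3))
  expect_equal(estimateLod(s2$reports, s2$truths, panel)$lod, 0.0025)
  s3 <- series(c("0" = 0, "0.0025" = 1, "0.005" = 2))
  r3 <- estimateLod(s3$reports, s3$truths, panel)
  expect_true(is.na(r3$lod))
  expect_equal(r3$status, "above-range")
  expect_equal(estimateLod(s3$reports, s3$truths, panel,
                           policy = "majority")$lod, 0.005)
  # false positives at 0% make the LoD undefined
  bad <- series(c("0" = 3, "0.005" = 3))
  bad$reports[1:3] <- lapply(1:3, function(i) mkreport("mut01", TRUE))
  expect_error(estimateLod(bad$reports, bad$truths, panel), "false")
})
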