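test_that("call strings parse, canonicalize and flag malformed tokens", {
  df <- parseCallString("BRAF:V600E:c.1799T>A;MAP2K1:P124S:c.370C>T")
  expect_equal(df$gene, c("BRAF", "MAP2K1"))
  expect_equal(nrow(parseCallString("WT")), 0L)
  expect_null(parseCallString(NA))
  expect_error(parseCallString("BRAF:V600E"), "malformed")
})

test_that("the reconstructed cohort reproduces the published biochip accounting", {
  rec <- referenceCohort()
  expect_equal(nrow(rec), 253L)
  fs <- summarizeCohort(rec, "biochip")
  expect_equal(fs$n_positive, 177L)
  expect_equal(fs$pct_positive, 70.0)
  expect_equal(fs$n_wt, 76L)
  g <- setNames(fs$genes$n, fs$genes$gene)
  expect_equal(g[c("BRAF", "NRAS", "KIT", "GNAQ", "GNA11", "MAP2K1")],
               c(BRAF = 129L, NRAS = 45L, KIT = 6L, GNAQ = 4L,
                 GNA11 = 2L, MAP2K1 = 2L))
  expect_equal(fs$genes$pct[fs$genes$gene == "BRAF"], 51.0)
  expect_equal(fs$genes$pct[fs$genes$gene == "NRAS"], 17.8)
})

test_that("pooling all methods adds the sequencing-only rare variants", {
  fa <- summarizeCohort(referenceCohort(), "any")
  g <- setNames(fa$genes$n, fa$genes$gene)
  expect_equal(g[["BRAF"]], 134L)   # 129 biochip + 5 rare by sequencing
  expect_equal(fa$genes$pct[fa$genes$gene == "BRAF"], 53.0)
  expect_equal(g[["GNAQ"]], 5L)
  v <- fa$variants
  expect_equal(sum(v$n[v$gene == "BRAF"]), 134L)
  expect_equal(v$share_pct[v$gene == "BRAF" &
                             v$cdna_change == "c.1799T>A"], 82.8)
  # one patient carries two NRAS mutations: 46 events in 45 patients
  expect_equal(sum(v$n[v$gene == "NRAS"]), 46L)
  expect_equal(g[["NRAS"]], 45L)
  expect_equal(v$share_pct[v$gene == "NRAS" &
                             v$cdna_change == "c.181C>A"], 43.5)
})

test_that("a cohort with no mutations summarizes to 100% wild type", {
  rec <- data.frame(sample_id = c("a", "b"), is_cell_line = FALSE,
                    biochip = "WT", stringsAsFactors = FALSE)
  fs <- summarizeCohort(rec, "biochip")
  expect_equal(fs$n_positive, 0L)
  expect_equal(fs$pct_wt, 100)
  expect_equal(nrow(fs$genes), 0L)
  expect_error(summarizeCohort(rec, "ngs"), "ngs")
})

test_that("biochip-vs-ARMS discordance and clamp+Sanger arbitration", {
  t3 <- armsDiscordantRecords()
  ct <- compareMethods(t3, "biochip", "arms")
  expect_equal(ct$summary$n_discordant, 10L)
  # discordance is symmetric in the two methods
  ct_rev <- compareMethods(t3, "arms", "biochip")
  expect_equal(sort(ct_rev$records$sample_id[!ct_rev$records$agree]),
               sort(ct$records$sample_id[!ct$records$agree]))
  res <- resolveDiscordance(ct, t3, arbiter = "clamp_sanger")
  expect_equal(as.vector(res$counts["confirms-a"]), 8L)
  # the two off-panel rare variants confirm neither method
  neither <- res$resolutions$sample_id[
    res$resolutions$resolution == "confirms-neither"]
  expect_setequal(neither, c("219", "238"))
  # an arbiter equal to method B everywhere confirms B everywhere
  t3b <- t3; t3b$clamp_sanger <- t3b$arms
  resb <- resolveDiscordance(compareMethods(t3b, "biochip", "arms"), t3b)
  expect_equal(as.vector(resb$counts["confirms-b"]), 10L)
  # identical call sets: zero discordance
  same <- t3; same$arms <- same$biochip
  expect_equal(compareMethods(same, "biochip", "arms")$summary$n_discordant,
               0L)
})

test_that("biochip-vs-NGS: biochip-only patients and NGS-only off-panel calls", {
  t4 <- ngsComparisonRecords()
  ct <- compareMethods(t4, "biochip", "ngs")
  s <- ct$summary
  expect_equal(s$n_compared, 31L)  # 25 patients + 6 cell lines
  # 4 patient samples with biochip-only BRAF/NRAS calls (Mel Cher excluded
  # as a cell line)
  expect_equal(s$n_samples_a_only_patients, 4L)
  per <- ct$records
  expect_setequal(per$sample_id[!per$is_cell_line & per$n_a_only > 0],
                  c("93", "96", "106", "112"))
  # 5 samples with NGS-only germline/off-panel variants
  expect_equal(s$n_samples_b_only, 5L)
  expect_setequal(per$sample_id[per$n_b_only > 0],
                  c("101", "106", "111", "SK-MEL2", "Mel Il"))
  # restricting to panel-representable variants removes the NGS-only calls
  ctp <- compareMethods(t4, "biochip", "ngs", restrict_to_panel = TRUE)
  expect_equal(ctp$summary$n_samples_b_only, 0L)
})

test_that("association tests reproduce the published contingency p-values", {
  rec <- referenceCohort()
  sex <- associationTests(rec, "sex", "BRAF", method = "any",
                          levels = c("F", "M"))
  expect_equal(as.vector(sex$table), c(85, 55, 46, 51))
  expect_lt(abs(sex$p_value - 0.047), 5e-3)
  nras_sex <- associationTests(rec, "sex", "NRAS", levels = c("M", "F"))
  expect_lt(abs(nras_sex$p_value - 0.0813), 5e-3)
  sub_f <- associationTests(rec, "subtype", "NRAS",
                            levels = c("nodular", "superficial"))
  expect_equal(as.vector(sub_f$table), c(7, 36, 0, 24))
  # the printed 0.0367 for this table corresponds to the uncorrected
  # chi-square; Fisher gives 0.0441
  expect_lt(abs(sub_f$p_value - 0.0441), 1e-3)
  sub_c <- associationTests(rec, "subtype", "NRAS",
                            levels = c("nodular", "superficial"),
                            test = "chisq-uncorrected")
  expect_lt(abs(sub_c$p_value - 0.0367), 5e-3)
  # identical proportions give Fisher p = 1
  even <- recordsFromTable(5, 5, 10, 10)
  expect_equal(associationTests(even, "sex", "BRAF",
                                levels = c("F", "M"))$p_value, 1)
  # degenerate margins raise
  expect_error(associationTests(recordsFromTable(0, 0, 5, 5), "sex",
                                "BRAF", levels = c("F", "M")),
               "degenerate")
})

test_that("numeric covariates route to the Mann-Whitney test", {
  co <- generateCohort(200, seed = 21)
  res <- associationTests(co, "age", "BRAF", method = "biochip")
  expect_equal(res$method, "mann-whitney")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("Fisher path agrees with hypergeometric enumeration", {
  # exhaustive small grid routed through the record-building path
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0) next
    rec <- recordsFromTable(a, b, c, d)
    p <- associationTests(rec, "sex", "BRAF", levels = c("F", "M"))$p_value
    expect_equal(p, fisherEnumOracle(a, b, c, d), tolerance = 1e-9,
                 info = paste(a, b, c, d))
  }
  # seeded random tables with margins up to 30
  set.seed(17)
  for (i in 1:100) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0) next
    rec <- recordsFromTable(a, b, c, d)
    p <- associationTests(rec, "sex", "BRAF", levels = c("F", "M"))$p_value
    expect_equal(p, fisherEnumOracle(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("cohort CSVs round-trip through disk", {
  rec <- referenceCohort()
  path <- withr::local_tempfile(fileext = ".csv")
  writeCohort(rec, path)
  rec2 <- readCohort(path)
  expect_equal(rec2$biochip, rec$biochip)
  expect_equal(rec2$clamp_sanger, rec$clamp_sanger)
  expect_equal(rec2$sex, rec$sex)
})
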