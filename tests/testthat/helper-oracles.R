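# Independent oracles used by the property tests. These deliberately
# re-derive the rules with straightforward loops, not by calling package
# internals.

# Brute-force re-statement of the group calling rule.
bruteCallOracle <- function(j_wt, j_mut, min_sbr = 2) {
  if (is.na(j_wt)) return(list(verdict = "no-call", which = NA_integer_))
  ok <- which(!is.na(j_mut) & j_mut > j_wt & j_mut >= min_sbr)
  if (!length(ok)) return(list(verdict = "WT", which = NA_integer_))
  best <- ok[j_mut[ok] == max(j_mut[ok])]
  if (length(best) > 1L) return(list(verdict = "no-call",
                                     which = NA_integer_))
  list(verdict = "mutant", which = best)
}

# Build an aggregateGroups-style table for one group from raw J values.
makeGroupSignal <- function(j_wt, j_mut, group_id = "G", gene = "BRAF") {
  n <- length(j_mut)
  data.frame(group_id = group_id,
             probe_id = c("wtp", paste0("m", seq_len(n))),
             role = c("wt", rep("mut", n)), gene = gene,
             protein_change = c(NA, paste0("X", seq_len(n), "Y")),
             cdna_change = c(NA, paste0("c.", seq_len(n), "A>T")),
             J = c(j_wt, j_mut), n_spots = 2L, flags = "",
             J_norm = NA_real_, stringsAsFactors = FALSE)
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# the table's margins, using binomial coefficients directly.
fisherEnumOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  xs <- max(0, k - n):min(m, k)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(N, k)
  p_obs <- pr[xs == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Cohort records realizing a 2x2 table of (mutated x covariate level).
recordsFromTable <- function(a, b, c, d, gene = "BRAF") {
  tok <- paste0(gene, ":V600E:c.1799T>A")
  data.frame(
    sample_id = as.character(seq_len(a + b + c + d)),
    is_cell_line = FALSE,
    biochip = c(rep(tok, a), rep("WT", c), rep(tok, b), rep("WT", d)),
    sex = c(rep("F", a + c), rep("M", b + d)),
    stringsAsFactors = FALSE)
}

# One synthetic noiseless chip + its truth, shared across imaging tests.
noiselessChip <- function(probe_id = "mut01", fraction = 0.005,
                          panel = defaultPanel(),
                          layout = buildLayout(panel)) {
  truth <- sampleTruth(if (fraction > 0) probe_id else character(0),
                       fraction)
  prods <- simulateClampPcr(truth, panel)
  st <- simulateSpotTruth(prods, layout, hybParams(cv = 0))
  img <- renderChipImage(st, layout, imageParams(pixel_sd = 0))
  list(image = img, spots = st$noiseless, layout = layout, panel = panel)
}
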