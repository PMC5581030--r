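METHOD_COLUMNS <- c("biochip", "arms", "sanger", "clamp_sanger", "ngs")

#' Parse a semicolon-joined call string
#'
#' Method calls are stored as \code{"GENE:PROT:c.change;GENE:PROT:c.change"},
#' \code{"WT"} for a tested wild-type result, and \code{NA}/empty for "not
#' tested by this method".
#'
#' @param x call string.
#' @return data.frame \code{gene}, \code{protein_change},
#'   \code{cdna_change}; zero rows for WT; \code{NULL} for a missing call.
#' @export
parseCallString <- function(x) {
  if (is.na(x) || x == "") return(NULL)
  empty <- data.frame(gene = character(0), protein_change = character(0),
                      cdna_change = character(0), stringsAsFactors = FALSE)
  if (x == "WT") return(empty)
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed call token in ", sQuote(x))
  do.call(rbind, lapply(parts, function(p)
    data.frame(gene = p[1], protein_change = p[2], cdna_change = p[3],
               stringsAsFactors = FALSE)))
}

## Canonical identity tokens (gene + canonical HGVS-c) of one method call.
## character(0) for WT, NA for missing.
callTokens <- function(x) {
  df <- parseCallString(x)
  if (is.null(df)) return(NA_character_)
  if (nrow(df) == 0L) return(character(0))
  paste(df$gene, vapply(df$cdna_change, canonicalHgvsC, character(1)),
        sep = ":")
}

#' Read / write a cohort record table (CSV)
#'
#' One row per sample; method-call columns (\code{biochip}, \code{arms},
#' \code{sanger}, \code{clamp_sanger}, \code{ngs}) hold semicolon-joined
#' \code{gene:protein:cdna} tokens, \code{"WT"}, or empty for untested;
#' remaining columns are clinical covariates.
#'
#' @param path CSV path.
#' @export
readCohort <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character"))
  for (cl in names(rec))  # empty cells mean missing / untested
    if (is.character(rec[[cl]]))
      rec[[cl]][!is.na(rec[[cl]]) & rec[[cl]] == ""] <- NA_character_
  if (!"is_cell_line" %in% names(rec)) rec$is_cell_line <- FALSE
  rec
}

#' @rdname readCohort
#' @param records cohort data.frame.
#' @export
writeCohort <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Packaged transcription of the discordant biochip-vs-ARMS samples
#' @return cohort-format data.frame of the ten discordant samples with
#'   biochip, ARMS, Sanger and clamp-plus-Sanger calls.
#' @export
armsDiscordantRecords <- function()
  readCohort(system.file("extdata", "arms_discordant.csv",
                         package = "melanochip", mustWork = TRUE))

#' Packaged transcription of the biochip-vs-NGS comparison samples
#' @return cohort-format data.frame of 25 patient samples and 6 melanoma
#'   cell lines with biochip and NGS calls.
#' @export
ngsComparisonRecords <- function()
  readCohort(system.file("extdata", "ngs_comparison.csv",
                         package = "melanochip", mustWork = TRUE))

#' Reconstruct the 253-patient cohort from the published marginals
#'
#' Builds, deterministically and in code, a per-patient record table whose
#' marginal counts reproduce every published cohort figure: the per-variant
#' biochip counts (129 BRAF / 45 NRAS / 6 KIT / 4 GNAQ / 2 GNA11 / 2 MAP2K1
#' positive patients, 177 biochip-positive, 76 wild type), the five rare
#' BRAF and one rare GNAQ variants found only by sequencing, the NRAS
#' double-mutant patient (Q61K with silent G60G), the sex margins (140
#' female / 97 male / 16 unknown; BRAF carriers 85 F vs 46 M, NRAS carriers
#' 19 F vs 22 M) and the subtype margins (43 nodular with 7 NRAS, 24
#' superficial spreading with none).
#'
#' The per-patient arrangement underneath those marginals (which individual
#' carries which variant and covariate) is a synthetic assignment: the
#' published per-gene counts over the mutually exclusive genes sum to 186,
#' nine more than the 177 mutation-positive patients, and the overlap is
#' absorbed here as nine BRAF+NRAS co-occurrences. Ages and remaining
#' covariates are left \code{NA} (only cohort-level summaries of them were
#' published).
#'
#' @return cohort data.frame with 253 rows.
#' @export
referenceCohort <- function() {
  tok <- function(gene, prot, cdna) paste(gene, prot, cdna, sep = ":")
  biochip <- rep("WT", 253)
  add <- function(calls, ids, token)
    ifelse(seq_along(calls) %in% ids,
           ifelse(calls == "WT", token, paste(calls, token, sep = ";")),
           calls)
  biochip <- add(biochip, 1:111, tok("BRAF", "V600E", "c.1799T>A"))
  biochip <- add(biochip, 112:125,
                 tok("BRAF", "V600K", "c.1798_1799delGTinsAA"))
  biochip <- add(biochip, 126:128,
                 tok("BRAF", "V600R", "c.1798_1799delGTinsAG"))
  biochip <- add(biochip, 129, tok("BRAF", "V600M", "c.1798G>A"))
  nras <- c(rep(tok("NRAS", "Q61K", "c.181C>A"), 20),
            rep(tok("NRAS", "Q61R", "c.182A>G"), 17),
            rep(tok("NRAS", "Q61L", "c.182A>T"), 3),
            rep(tok("NRAS", "Q61H", "c.183A>C"), 2),
            tok("NRAS", "Q61H", "c.183A>T"),
            tok("NRAS", "G13R", "c.37G>C"),
            tok("NRAS", "G13D", "c.38G>A"))
  nras_ids <- c(1:9, 130:165)  # nine BRAF+NRAS co-occurrences, 36 NRAS-only
  for (k in seq_along(nras_ids))
    biochip <- add(biochip, nras_ids[k], nras[k])
  biochip <- add(biochip, 166:170, tok("KIT", "L576P", "c.1727T>C"))
  biochip <- add(biochip, 171, tok("KIT", "K642E", "c.1924A>G"))
  biochip <- add(biochip, 172:173, tok("GNAQ", "Q209P", "c.626A>C"))
  biochip <- add(biochip, 174:175, tok("GNAQ", "Q209L", "c.626A>T"))
  biochip <- add(biochip, 176:177, tok("GNA11", "Q209L", "c.626A>T"))
  biochip <- add(biochip, 10:11, tok("MAP2K1", "P124S", "c.370C>T"))

  clamp_sanger <- rep(NA_character_, 253)
  clamp_sanger[178] <- tok("BRAF", "V600D", "c.1799_1800TG>AC")
  clamp_sanger[179] <- tok("BRAF", "V600V", "c.1800G>A")
  clamp_sanger[180] <- tok("BRAF", "A598V", "c.1793C>T")
  clamp_sanger[181] <- tok("BRAF", "A598_T599insV", "c.1794_1795insGTT")
  clamp_sanger[182] <- tok("BRAF", "T599_V600insT", "c.1797_1798insACA")
  sanger <- rep(NA_character_, 253)
  sanger[183] <- tok("GNAQ", "Q209L", "c.625_626CA>TT")
  sanger[130] <- paste(tok("NRAS", "Q61K", "c.181C>A"),
                       tok("NRAS", "G60G", "c.180A>T"), sep = ";")

  sex <- rep(NA_character_, 253)
  sex[c(1:4, 10:90, 130:144, 166:177, 183:210)] <- "F"
  sex[c(5:8, 91:129, 178:180, 145:162, 211:243)] <- "M"

  subtype <- rep(NA_character_, 253)
  subtype[c(130:136, 183:218)] <- "nodular"
  subtype[46:69] <- "superficial"
  subtype[219:228] <- "lentigo"
  subtype[229] <- "acral"

  data.frame(sample_id = as.character(1:253), is_cell_line = FALSE,
             biochip = biochip, sanger = sanger,
             clamp_sanger = clamp_sanger, sex = sex, age = NA_real_,
             subtype = subtype, stringsAsFactors = FALSE)
}

## Per-record canonical token sets for one method ("any" = union over all
## method columns present; NA when the record was tested by no method).
recordTokens <- function(records, method) {
  if (method == "any") {
    cols <- intersect(METHOD_COLUMNS, names(records))
    if (!length(cols)) stop("no method columns in records")
    lapply(seq_len(nrow(records)), function(i) {
      tks <- lapply(cols, function(cl) callTokens(records[[cl]][i]))
      tks <- tks[!vapply(tks, function(t) length(t) == 1L && is.na(t),
                         logical(1))]
      if (!length(tks)) return(NA_character_)
      unique(unlist(tks))
    })
  } else {
    if (!method %in% names(records))
      stop("unknown method ", sQuote(method))
    lapply(records[[method]], callTokens)
  }
}

isMissingTokens <- function(t) length(t) == 1L && is.na(t[1])

#' Cohort mutation-frequency summary
#'
#' Counts, per gene and per exact variant, the samples carrying at least
#' one mutation according to the chosen method (\code{"any"} pools all
#' method columns). Cell lines are excluded by default. Percentages use the
#' cohort size as denominator and are rounded to one decimal; a variant's
#' share is taken over all mutation events of its gene.
#'
#' @param records cohort data.frame.
#' @param method a method column name or \code{"any"}.
#' @param include_cell_lines logical.
#' @return list of class \code{freq_table}: \code{denominator},
#'   \code{n_positive}, \code{pct_positive}, \code{n_wt}, \code{pct_wt},
#'   \code{genes} (gene, n, pct), \code{variants} (gene, cdna_change, n,
#'   share_pct).
#' @export
summarizeCohort <- function(records, method = "biochip",
                            include_cell_lines = FALSE) {
  stopifnot(nrow(records) > 0L)
  if (!include_cell_lines)
    records <- records[!records$is_cell_line, , drop = FALSE]
  toks <- recordTokens(records, method)
  toks <- toks[!vapply(toks, isMissingTokens, logical(1))]
  denom <- length(toks)
  if (denom == 0L) stop("no record carries a ", sQuote(method), " call")
  pos <- vapply(toks, function(t) length(t) > 0L, logical(1))
  gene_of <- function(t) sub(":.*$", "", t)
  gene_counts <- table(unlist(lapply(toks, function(t) unique(gene_of(t)))))
  var_counts <- table(unlist(toks))
  genes <- data.frame(gene = as.character(names(gene_counts)),
                      n = as.integer(gene_counts), stringsAsFactors = FALSE)
  genes <- genes[order(-genes$n, genes$gene), ]
  genes$pct <- round(100 * genes$n / denom, 1)
  vt <- strsplit(as.character(names(var_counts)), ":", fixed = TRUE)
  variants <- data.frame(gene = vapply(vt, `[`, "", 1),
                         cdna_change = vapply(vt, `[`, "", 2),
                         n = as.integer(var_counts),
                         stringsAsFactors = FALSE)
  gene_var_tot <- tapply(variants$n, variants$gene, sum)
  variants$share_pct <- round(100 * variants$n /
                                as.numeric(gene_var_tot[variants$gene]), 1)
  variants <- variants[order(variants$gene, -variants$n), ]
  rownames(genes) <- rownames(variants) <- NULL
  structure(list(method = method, denominator = denom,
                 n_positive = sum(pos),
                 pct_positive = round(100 * sum(pos) / denom, 1),
                 n_wt = sum(!pos),
                 pct_wt = round(100 * sum(!pos) / denom, 1),
                 genes = genes, variants = variants),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("Cohort summary (%s): %d samples, %d (%.1f%%) mutated, %d (%.1f%%) WT\n",
              x$method, x$denominator, x$n_positive, x$pct_positive,
              x$n_wt, x$pct_wt))
  print(x$genes, row.names = FALSE)
  invisible(x)
}

#' Pairwise cross-method concordance
#'
#' A record is compared when both methods report a call; it is discordant
#' when the two canonical call sets differ (optionally after restricting
#' both to panel-representable variants).
#'
#' @param records cohort data.frame.
#' @param method_a,method_b method column names.
#' @param restrict_to_panel drop off-panel variants before comparing.
#' @param panel panel used for the restriction.
#' @return list of class \code{concordance_table}: \code{records} (per
#'   sample: call strings, \code{agree}, \code{n_a_only}, \code{n_b_only},
#'   \code{is_cell_line}) and a \code{summary} (n compared / discordant and
#'   the A-only / B-only sample counts, cell lines excluded from the
#'   patient-sample counts).
#' @export
compareMethods <- function(records, method_a, method_b,
                           restrict_to_panel = FALSE,
                           panel = defaultPanel()) {
  ta <- recordTokens(records, method_a)
  tb <- recordTokens(records, method_b)
  keep <- !(vapply(ta, isMissingTokens, logical(1)) |
              vapply(tb, isMissingTokens, logical(1)))
  if (!any(keep)) stop("no record carries both methods")
  rec <- records[keep, , drop = FALSE]
  ta <- ta[keep]; tb <- tb[keep]
  if (restrict_to_panel) {
    e <- panelEntries(panel)
    ptok <- paste(e$gene, e$cdna_change, sep = ":")
    ta <- lapply(ta, intersect, ptok)
    tb <- lapply(tb, intersect, ptok)
  }
  per <- data.frame(
    sample_id = rec$sample_id, is_cell_line = rec$is_cell_line,
    call_a = vapply(ta, paste, "", collapse = ";"),
    call_b = vapply(tb, paste, "", collapse = ";"),
    agree = mapply(setequal, ta, tb),
    n_a_only = mapply(function(a, b) length(setdiff(a, b)), ta, tb),
    n_b_only = mapply(function(a, b) length(setdiff(b, a)), ta, tb),
    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  pat <- !per$is_cell_line
  structure(list(
    method_a = method_a, method_b = method_b, records = per,
    summary = list(
      n_compared = nrow(per),
      n_discordant = sum(!per$agree),
      n_samples_a_only_patients = sum(pat & per$n_a_only > 0),
      n_samples_b_only_patients = sum(pat & per$n_b_only > 0),
      n_samples_a_only = sum(per$n_a_only > 0),
      n_samples_b_only = sum(per$n_b_only > 0))),
    class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Concordance %s vs %s: %d compared, %d discordant (%d %s-only, %d %s-only samples)\n",
              x$method_a, x$method_b, s$n_compared, s$n_discordant,
              s$n_samples_a_only, x$method_a, s$n_samples_b_only,
              x$method_b))
  invisible(x)
}

#' Arbitrate discordant records with a third method
#'
#' Each discordant record is labeled by exact call-set equality with the
#' arbiter: \code{confirms-a}, \code{confirms-b}, \code{confirms-neither}
#' (the arbiter saw something else, e.g. an off-panel variant at a site the
#' chip cannot represent) or \code{unresolved} (no arbiter call).
#'
#' @param table a \code{concordance_table} from \code{\link{compareMethods}}.
#' @param records the cohort data.frame the table was built from.
#' @param arbiter arbiter method column (default \code{"clamp_sanger"}).
#' @return list: per-record \code{resolutions} data.frame and \code{counts}.
#' @export
resolveDiscordance <- function(table, records, arbiter = "clamp_sanger") {
  stopifnot(inherits(table, "concordance_table"))
  disc <- table$records[!table$records$agree, , drop = FALSE]
  arb_all <- recordTokens(records, arbiter)
  names(arb_all) <- records$sample_id
  lab <- vapply(seq_len(nrow(disc)), function(i) {
    arb <- arb_all[[disc$sample_id[i]]]
    if (is.null(arb) || isMissingTokens(arb)) return("unresolved")
    ## call_a / call_b already hold canonical gene:cdna tokens
    a <- if (disc$call_a[i] == "") character(0) else
      strsplit(disc$call_a[i], ";", fixed = TRUE)[[1]]
    b <- if (disc$call_b[i] == "") character(0) else
      strsplit(disc$call_b[i], ";", fixed = TRUE)[[1]]
    if (setequal(arb, a)) "confirms-a"
    else if (setequal(arb, b)) "confirms-b"
    else "confirms-neither"
  }, character(1))
  res <- cbind(disc, resolution = lab, stringsAsFactors = FALSE)
  counts <- table(factor(lab, levels = c("confirms-a", "confirms-b",
                                         "confirms-neither", "unresolved")))
  list(resolutions = res, counts = counts)
}

#' Association between mutation status and a clinical covariate
#'
#' Builds the mutation indicator for one gene (any variant by the chosen
#' method), drops records with a missing covariate, and tests association:
#' two-sided Fisher exact test (default) or chi-squared with Yates
#' continuity correction on the 2x2 table for categorical covariates, and
#' the Mann-Whitney (Wilcoxon rank-sum) test for numeric covariates such as
#' age.
#'
#' @param records cohort data.frame.
#' @param covariate covariate column name.
#' @param gene panel gene symbol.
#' @param method method column or \code{"any"} (default).
#' @param test \code{"fisher"} (default), \code{"chisq"} (Yates-corrected),
#'   \code{"chisq-uncorrected"} or \code{"wilcox"} (numeric covariates
#'   always use \code{"wilcox"}).
#' @param levels for categorical covariates, the two levels to compare
#'   (default: the two most frequent).
#' @return list: \code{p_value}, \code{method}, \code{table} (2x2 counts,
#'   mutated x covariate level) or group sizes, \code{n}.
#' @export
associationTests <- function(records, covariate, gene, method = "any",
                             test = c("fisher", "chisq",
                                      "chisq-uncorrected", "wilcox"),
                             levels = NULL) {
  test <- match.arg(test)
  records <- records[!records$is_cell_line, , drop = FALSE]
  toks <- recordTokens(records, method)
  tested <- !vapply(toks, isMissingTokens, logical(1))
  mutated <- vapply(toks, function(t)
    !isMissingTokens(t) && any(startsWith(t, paste0(gene, ":"))),
    logical(1))
  cov <- records[[covariate]]
  keep <- tested & !is.na(cov)
  cov <- cov[keep]; mutated <- mutated[keep]
  if (is.numeric(cov)) {
    if (length(unique(mutated)) < 2L)
      stop("degenerate grouping: all records on one side")
    ht <- stats::wilcox.test(cov ~ factor(mutated,
                                          levels = c(TRUE, FALSE)))
    return(list(p_value = ht$p.value, method = "mann-whitney",
                table = table(mutated), n = length(cov)))
  }
  if (is.null(levels))
    levels <- names(sort(table(cov), decreasing = TRUE))[1:2]
  sel <- cov %in% levels
  cov <- factor(cov[sel], levels = levels)
  mutated <- factor(mutated[sel], levels = c(TRUE, FALSE))
  tab <- table(mutated, cov)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("degenerate contingency table: empty margin")
  ht <- switch(test,
    chisq = suppressWarnings(stats::chisq.test(tab, correct = TRUE)),
    `chisq-uncorrected` = suppressWarnings(stats::chisq.test(tab,
                                                             correct = FALSE)),
    stats::fisher.test(tab))
  list(p_value = ht$p.value,
       method = switch(test, chisq = "chisq-yates",
                       `chisq-uncorrected` = "chisq",
                       "fisher-two-sided"),
       table = tab, n = sum(tab))
}
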