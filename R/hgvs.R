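#' Parse an HGVS coding-DNA change
#'
#' Parses the subset of HGVS c. notation used on the panel: single-base
#' substitutions (\code{c.1799T>A}), deletion-insertions
#' (\code{c.1798_1799delGTinsAA}, also accepted in the range-substitution
#' spelling \code{c.1799_1800TG>AC}) and insertions
#' (\code{c.1797_1798insACA}).
#'
#' @param text an HGVS c. string, e.g. \code{"c.1799T>A"}.
#' @return a list of class \code{hgvs_c} with elements \code{kind}
#'   (\code{"substitution"}, \code{"delins"} or \code{"insertion"}),
#'   \code{start}, \code{end} (1-based CDS positions), \code{ref}
#'   (\code{NA} for insertions) and \code{alt}.
#' @details Positions are 1-based on the coding strand; codon \code{c} spans
#'   CDS positions \code{3c-2 .. 3c}. \code{formatHgvsC} gives the canonical
#'   spelling; parse-then-format is the identity on canonical input.
#' @examples
#' parseHgvsC("c.1799T>A")
#' parseHgvsC("c.1798_1799delGTinsAA")
#' @export
parseHgvsC <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!startsWith(text, "c."))
    stop("HGVS c. change must begin with 'c.': ", sQuote(text))
  body <- substr(text, 3L, nchar(text))
  mk <- function(kind, start, end, ref, alt) {
    if (end < start)
      stop("inverted position range in ", sQuote(text))
    if (!is.na(ref) && !grepl("^[ACGT]+$", ref))
      stop("invalid reference base(s) ", sQuote(ref), " in ", sQuote(text))
    if (!grepl("^[ACGT]+$", alt))
      stop("invalid alternate base(s) ", sQuote(alt), " in ", sQuote(text))
    structure(list(kind = kind, start = start, end = end, ref = ref,
                   alt = alt), class = "hgvs_c")
  }
  m <- regmatches(body, regexec("^(\\d+)([A-Za-z])>([A-Za-z])$", body))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2])
    return(mk("substitution", pos, pos, m[3], m[4]))
  }
  m <- regmatches(body,
        regexec("^(\\d+)_(\\d+)del([A-Za-z]+)ins([A-Za-z]+)$", body))[[1]]
  if (length(m)) {
    s <- as.integer(m[2]); e <- as.integer(m[3])
    if (e >= s && nchar(m[4]) != e - s + 1L)
      stop("deleted bases ", sQuote(m[4]), " do not span ", s, "_", e,
           " in ", sQuote(text))
    return(mk("delins", s, e, m[4], m[5]))
  }
  m <- regmatches(body,
        regexec("^(\\d+)_(\\d+)([A-Za-z]+)>([A-Za-z]+)$", body))[[1]]
  if (length(m)) {
    s <- as.integer(m[2]); e <- as.integer(m[3])
    if (e >= s && nchar(m[4]) != e - s + 1L)
      stop("reference bases ", sQuote(m[4]), " do not span ", s, "_", e,
           " in ", sQuote(text))
    return(mk("delins", s, e, m[4], m[5]))
  }
  m <- regmatches(body, regexec("^(\\d+)_(\\d+)ins([A-Za-z]+)$", body))[[1]]
  if (length(m)) {
    s <- as.integer(m[2]); e <- as.integer(m[3])
    if (e != s + 1L)
      stop("insertion positions must be adjacent in ", sQuote(text))
    return(mk("insertion", s, e, NA_character_, m[4]))
  }
  stop("malformed HGVS c. syntax: ", sQuote(text))
}

#' Canonical spelling of a parsed HGVS coding change
#'
#' @param change an \code{hgvs_c} list from \code{\link{parseHgvsC}}.
#' @return the canonical HGVS c. string.
#' @export
formatHgvsC <- function(change) {
  stopifnot(inherits(change, "hgvs_c"))
  switch(change$kind,
    substitution = sprintf("c.%d%s>%s", change$start, change$ref,
                           change$alt),
    delins = sprintf("c.%d_%ddel%sins%s", change$start, change$end,
                     change$ref, change$alt),
    insertion = sprintf("c.%d_%dins%s", change$start, change$end,
                        change$alt))
}

#' Canonicalize an HGVS c. string (parse then format)
#' @param text an HGVS c. string.
#' @export
canonicalHgvsC <- function(text) formatHgvsC(parseHgvsC(text))

#' Load the packaged reference codon windows
#'
#' Short coding-strand CDS windows around the codons interrogated by the
#' panel, used to check that each entry's HGVS coding change and protein
#' label agree. Windows are frame-aligned (\code{cds_start} is the first
#' base of a codon).
#'
#' @param path optional TSV overriding the packaged windows.
#' @return data.frame with columns \code{gene}, \code{region},
#'   \code{cds_start}, \code{sequence}.
#' @export
codonContexts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "codon_contexts.tsv",
                        package = "melanochip", mustWork = TRUE)
  ctx <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all((ctx$cds_start - 1L) %% 3L == 0L),
            all(nchar(ctx$sequence) %% 3L == 0L))
  ctx
}

## Apply a parsed coding change to a CDS window given in window coordinates.
applyChangeToWindow <- function(seq, cds_start, change) {
  n <- nchar(seq)
  off <- change$start - cds_start + 1L
  end <- change$end - cds_start + 1L
  if (off < 1L || end > n)
    stop("change positions ", change$start, "_", change$end,
         " outside the context window")
  if (change$kind == "insertion")
    return(paste0(substr(seq, 1L, off), change$alt, substr(seq, end, n)))
  ref_obs <- substr(seq, off, end)
  if (ref_obs != change$ref)
    stop("reference mismatch at CDS ", change$start, ": window has ",
         sQuote(ref_obs), ", change expects ", sQuote(change$ref))
  paste0(substr(seq, 1L, off - 1L), change$alt, substr(seq, end + 1L, n))
}

translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("cannot translate codon ", sQuote(codon))
  aa
}

parseProteinLabel <- function(label) {
  m <- regmatches(label, regexec("^([A-Z])(\\d+)([A-Z])$", label))[[1]]
  if (!length(m)) stop("unsupported protein-change label ", sQuote(label))
  list(aa_ref = m[2], codon_number = as.integer(m[3]), aa_alt = m[4])
}

#' Check one panel entry against its reference codon window
#'
#' Applies the entry's HGVS coding change to the packaged coding-strand
#' window, translates the affected codon with the standard genetic code, and
#' confirms the protein label (reference amino acid, codon number, alternate
#' amino acid).
#'
#' @param entry one-row data.frame (or list) with \code{gene},
#'   \code{protein_change}, \code{cdna_change}.
#' @param contexts codon-window table from \code{\link{codonContexts}}.
#' @return list with \code{status} (\code{"consistent"},
#'   \code{"inconsistent"} or \code{"not-checked"} for frame-shifting
#'   insertions), the reference and mutant codon strings and the observed
#'   amino acids.
#' @export
validateEntry <- function(entry, contexts = codonContexts()) {
  lab <- parseProteinLabel(entry$protein_change)
  chg <- parseHgvsC(entry$cdna_change)
  c_start <- 3L * lab$codon_number - 2L
  c_end <- 3L * lab$codon_number
  ctx <- contexts[contexts$gene == entry$gene &
                  contexts$cds_start <= c_start &
                  contexts$cds_start + nchar(contexts$sequence) - 1L >=
                    max(c_end, chg$end), , drop = FALSE]
  if (nrow(ctx) == 0L)
    stop("no codon context covers ", entry$gene, " codon ",
         lab$codon_number)
  ctx <- ctx[1L, ]
  getCodon <- function(seq) {
    off <- c_start - ctx$cds_start + 1L
    substr(seq, off, off + 2L)
  }
  ref_codon <- getCodon(ctx$sequence)
  aa_ref_obs <- translateCodon(ref_codon)
  if (chg$kind == "insertion")
    return(list(status = "not-checked", ref_codon = ref_codon,
                mut_codon = NA_character_, aa_ref_obs = aa_ref_obs,
                aa_alt_obs = NA_character_))
  if (chg$start < c_start || chg$end > c_end)
    stop(entry$gene, " ", entry$cdna_change,
         " does not lie within codon ", lab$codon_number)
  mut_seq <- applyChangeToWindow(ctx$sequence, ctx$cds_start, chg)
  mut_codon <- getCodon(mut_seq)
  aa_alt_obs <- translateCodon(mut_codon)
  ok <- (aa_ref_obs == lab$aa_ref) && (aa_alt_obs == lab$aa_alt)
  list(status = if (ok) "consistent" else "inconsistent",
       ref_codon = ref_codon, mut_codon = mut_codon,
       aa_ref_obs = aa_ref_obs, aa_alt_obs = aa_alt_obs)
}

#' Validate every entry of a panel
#'
#' @param panel a \code{\link{MutationPanel}}.
#' @param contexts codon-window table from \code{\link{codonContexts}}.
#' @return data.frame: one row per entry with the \code{validateEntry}
#'   verdict fields.
#' @export
validatePanel <- function(panel, contexts = codonContexts()) {
  e <- panelEntries(panel)
  out <- lapply(seq_len(nrow(e)), function(i)
    as.data.frame(validateEntry(e[i, ], contexts),
                  stringsAsFactors = FALSE))
  cbind(e[, c("gene", "protein_change", "cdna_change")],
        do.call(rbind, out))
}
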