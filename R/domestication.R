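# Domestication: find internal type IIS recognition sites in a CDS and
# remove them with silent point mutations, preferring frequent codons.

#' Scan a sequence for type IIS recognition sites on both strands
#'
#' Reports every occurrence of each enzyme's recognition sequence on the
#' plus strand and (because type IIS recognition sites are non-palindromic)
#' of its reverse complement, i.e. sites on the minus strand. `start` is the
#' 0-based offset of the occurrence in plus-strand coordinates.
#'
#' @param seq strict DNA (`nt_sequence` or string)
#' @param enzymes list of `tiis_enzyme` (default BsaI and BbsI)
#' @return data.frame with columns `enzyme`, `strand` (`"+"`/`"-"`), `start`
#'   (0-based), `end` (exclusive), and list-column `overlapped_codons`
#'   (1-based codon indices intersecting the site), sorted by `start`
#' @export
scan_sites <- function(seq, enzymes = list(BSAI, BBSI)) {
  s <- as_dna_string(seq)
  if (!is_valid_dna(s, strict = TRUE))
    stop("scan_sites requires a strict A/C/G/T sequence", call. = FALSE)
  if (inherits(enzymes, "tiis_enzyme")) enzymes <- list(enzymes)
  rows <- list()
  subject <- Biostrings::DNAString(s)
  for (enz in enzymes) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") enz$recognition
             else reverse_complement(enz$recognition)
      if (nchar(s) < nchar(pat)) next
      m <- Biostrings::matchPattern(pat, subject)
      if (length(m) == 0L) next
      starts <- BiocGenerics::start(m) - 1L  # to 0-based
      for (st in starts) {
        len <- nchar(pat)
        codons <- seq.int(st %/% 3L + 1L, (st + len - 1L) %/% 3L + 1L)
        rows[[length(rows) + 1L]] <- list(enzyme = enz$name, strand = strand,
                                          start = st, end = st + len,
                                          overlapped_codons = codons)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(enzyme = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      overlapped_codons = I(list())))
  }
  df <- data.frame(
    enzyme = vapply(rows, `[[`, character(1), "enzyme"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    overlapped_codons = I(lapply(rows, `[[`, "overlapped_codons")))
  df <- df[order(df$start, df$enzyme, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# identity of a hit for set comparisons
hit_key <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  paste(hits$enzyme, hits$strand, hits$start, sep = ":")
}

#' Propose a silent single-codon fix that removes one recognition site
#'
#' Considers every synonymous substitution of every codon overlapped by the
#' hit, keeps those that destroy the site without creating any new BsaI or
#' BbsI site on either strand and whose replacement codon is not rare
#' (`fraction >= min_fraction`), and returns the one with the highest codon
#' usage; ties are broken by smallest codon index, then alphabetically.
#'
#' @param seq a CDS (`nt_sequence` with `is_cds = TRUE`, or plain in-frame
#'   string)
#' @param hit one row of [scan_sites()] output
#' @param usage a [codon_usage()] table
#' @param enzymes enzymes whose sites must not (re)appear
#' @param min_fraction reject synonymous codons rarer than this (default 0.05)
#' @return a one-row data.frame: `codon_index`, `old_codon`, `new_codon`,
#'   `usage_freq`
#' @export
propose_silent_fix <- function(seq, hit, usage = codon_usage("e_coli"),
                               enzymes = list(BSAI, BBSI),
                               min_fraction = 0.05) {
  s <- as_dna_string(seq)
  if (nchar(s) %% 3L != 0L)
    stop("sequence is not in frame (length not divisible by 3)", call. = FALSE)
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1L)
    codons <- hit$overlapped_codons[[1]]
    key <- hit_key(hit)
  } else stop("`hit` must be a one-row data.frame from scan_sites()",
              call. = FALSE)
  before <- hit_key(scan_sites(s, enzymes))
  if (!key %in% before)
    stop("hit ", key, " not present in sequence", call. = FALSE)

  n_codons <- nchar(s) %/% 3L
  best <- NULL
  for (ci in sort(codons)) {
    if (ci < 1L || ci > n_codons) next
    old <- codon_at(s, ci)
    aa <- GENETIC_CODE_TABLE[[old]]
    for (cand in sort(synonymous_codons(aa))) {
      if (cand == old) next
      fr <- usage_fraction(usage, cand)
      if (fr < min_fraction) next
      trial <- replace_codon(s, ci, cand)
      after <- hit_key(scan_sites(trial, enzymes))
      if (key %in% after) next            # site survives
      if (!all(after %in% setdiff(before, key))) next  # new site created
      if (is.null(best) || fr > best$usage_freq ||
          (fr == best$usage_freq && ci < best$codon_index) ||
          (fr == best$usage_freq && ci == best$codon_index &&
           cand < best$new_codon)) {
        best <- data.frame(codon_index = ci, old_codon = old,
                           new_codon = cand, usage_freq = fr)
      }
    }
  }
  if (is.null(best))
    stop("undomesticatable site: no silent single-codon substitution removes ",
         hit$enzyme, " site at offset ", hit$start, " (", hit$strand,
         " strand)", call. = FALSE)
  rownames(best) <- NULL
  best
}

#' Remove all internal BsaI/BbsI sites from a CDS by silent mutation
#'
#' Iteratively applies [propose_silent_fix()] until no recognition site of
#' either enzyme remains on either strand. The encoded protein is unchanged
#' and the operation is idempotent. Domestication has to be done only once
#' per gene, before library design.
#'
#' @inheritParams propose_silent_fix
#' @return list with `sequence` (domesticated `nt_sequence`) and `fixes`
#'   (data.frame of applied substitutions, possibly empty)
#' @export
domesticate <- function(seq, usage = codon_usage("e_coli"),
                        enzymes = list(BSAI, BBSI), min_fraction = 0.05) {
  is_cds <- inherits(seq, "nt_sequence") && attr(seq, "is_cds")
  desc <- if (inherits(seq, "nt_sequence")) attr(seq, "description") else ""
  s <- as_dna_string(seq)
  aa_before <- translate_dna(s)
  fixes <- list()
  repeat {
    hits <- scan_sites(s, enzymes)
    if (nrow(hits) == 0L) break
    if (length(fixes) > nchar(s))
      stop("domestication did not converge", call. = FALSE)  # unreachable guard
    fix <- propose_silent_fix(s, hits[1, , drop = FALSE], usage,
                              enzymes, min_fraction)
    s <- replace_codon(s, fix$codon_index, fix$new_codon)
    fixes[[length(fixes) + 1L]] <- fix
  }
  stopifnot(identical(translate_dna(s), aa_before))
  fixes <- if (length(fixes)) do.call(rbind, fixes) else
    data.frame(codon_index = integer(0), old_codon = character(0),
               new_codon = character(0), usage_freq = numeric(0))
  list(sequence = nt_sequence(s, description = desc, is_cds = is_cds),
       fixes = fixes)
}

#' Write a domestication fixes table to CSV or JSON
#'
#' @param fixes the `fixes` data.frame from [domesticate()]
#' @param path output file; format inferred from the extension
#'   (`.csv` or `.json`)
#' @return `path`, invisibly
#' @export
write_fixes <- function(fixes, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(fixes, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(fixes, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  } else stop("unsupported fixes format: .", ext, call. = FALSE)
  invisible(path)
}
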