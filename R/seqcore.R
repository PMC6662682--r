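# DNA sequence primitives: IUPAC alphabet, degenerate codons, translation,
# overhang arithmetic. All user-facing amino-acid positions are 1-based;
# internal nucleotide coordinates are 0-based, half-open.

#' IUPAC nucleotide codes and the strict bases each one stands for
#' @keywords internal
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Explicit complement table for all 15 IUPAC codes (e.g. D <-> H).
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

STRICT_BASES <- c("A", "C", "G", "T")

#' Test whether a string is a valid IUPAC (optionally strict) DNA string
#'
#' @param x character scalar
#' @param strict if `TRUE`, only A/C/G/T are allowed
#' @return logical scalar
#' @export
is_valid_dna <- function(x, strict = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) return(FALSE)
  if (nchar(x) == 0L) return(TRUE)
  alphabet <- if (strict) STRICT_BASES else names(IUPAC_COMPLEMENT)
  all(strsplit(toupper(x), "", fixed = TRUE)[[1]] %in% alphabet)
}

#' Construct a validated nucleotide sequence
#'
#' A light S3 wrapper around an upper-case DNA string. With `is_cds = TRUE`
#' the sequence must be a complete in-frame open reading frame: length
#' divisible by 3, starting with ATG, ending with a stop codon and with no
#' internal stop in frame 0.
#'
#' @param bases DNA string (IUPAC codes allowed unless `strict`)
#' @param description free-text description (FASTA header style)
#' @param is_cds assert and record coding-sequence semantics
#' @param strict restrict the alphabet to A/C/G/T
#' @return an object of class `nt_sequence` (a character scalar with
#'   `description` and `is_cds` attributes)
#' @export
nt_sequence <- function(bases, description = "", is_cds = FALSE,
                        strict = is_cds) {
  bases <- toupper(as.character(bases))
  if (!is_valid_dna(bases, strict = strict)) {
    stop("invalid ", if (strict) "strict " else "", "DNA string: characters ",
         "outside the ", if (strict) "A/C/G/T" else "IUPAC", " alphabet",
         call. = FALSE)
  }
  if (is_cds) {
    if (nchar(bases) %% 3L != 0L)
      stop("CDS length (", nchar(bases), ") is not divisible by 3", call. = FALSE)
    if (nchar(bases) < 6L)
      stop("CDS must contain at least a start and a stop codon", call. = FALSE)
    aa <- translate_dna(bases)
    if (substr(bases, 1L, 3L) != "ATG")
      stop("CDS does not begin with ATG", call. = FALSE)
    if (substr(aa, nchar(aa), nchar(aa)) != "*")
      stop("CDS does not end with a stop codon", call. = FALSE)
    if (grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE))
      stop("CDS contains an internal stop codon in frame 0", call. = FALSE)
  }
  structure(bases, class = "nt_sequence",
            description = description, is_cds = is_cds)
}

#' @export
print.nt_sequence <- function(x, ...) {
  n <- nchar(x)
  shown <- if (n > 60) paste0(substr(x, 1, 57), "...") else unclass(x)
  cat(sprintf("<nt_sequence%s> %d nt  %s\n",
              if (attr(x, "is_cds")) " CDS" else "", n, shown))
  if (nzchar(attr(x, "description")))
    cat("  ", attr(x, "description"), "\n", sep = "")
  invisible(x)
}

# Coerce nt_sequence or plain character to a bare, attribute-free string.
as_dna_string <- function(x) {
  if (inherits(x, "nt_sequence")) {
    attributes(x) <- NULL
    x
  } else {
    toupper(as.vector(x, "character"))
  }
}

#' Reverse complement of an IUPAC DNA string
#'
#' Degenerate codes map to their complement codes (e.g. D to H, R to Y).
#' The operation is an involution: `reverse_complement(reverse_complement(s))`
#' equals `s` for every IUPAC string.
#'
#' @param seq DNA string or `nt_sequence`
#' @return character scalar (reverse complement, 5' to 3')
#' @export
reverse_complement <- function(seq) {
  s <- as_dna_string(seq)
  if (!is_valid_dna(s)) stop("invalid IUPAC DNA string", call. = FALSE)
  if (nchar(s) == 0L) return(s)
  comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(IUPAC_COMPLEMENT, collapse = ""), s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Expand a degenerate codon into its strict codon set
#'
#' NDT expands to 12 codons (4 x 3 x 1), NNK to 32 (4 x 4 x 2); a strict
#' codon is its own expansion. The expansion size always equals the product
#' of the per-position code cardinalities.
#'
#' @param codon three IUPAC codes, e.g. `"NDT"`
#' @return character vector of strict codons, lexicographically sorted
#' @export
expand_degenerate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  if (nchar(codon) != 3L || !is_valid_dna(codon))
    stop("degenerate codon must be 3 valid IUPAC codes, got '", codon, "'",
         call. = FALSE)
  pos <- strsplit(codon, "", fixed = TRUE)[[1]]
  grid <- expand.grid(IUPAC_CODES[[pos[1]]], IUPAC_CODES[[pos[2]]],
                      IUPAC_CODES[[pos[3]]], stringsAsFactors = FALSE)
  sort(paste0(grid[[1]], grid[[2]], grid[[3]]))
}

#' Does a degenerate pattern admit a given strict string?
#' @keywords internal
iupac_matches <- function(pattern, strict) {
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  s <- strsplit(toupper(strict), "", fixed = TRUE)[[1]]
  if (length(p) != length(s)) return(FALSE)
  all(mapply(function(pc, sc) sc %in% IUPAC_CODES[[pc]], p, s))
}

#' Enumerate all valid 4 bp Golden Gate overhangs
#'
#' All 256 4-mers minus the 16 palindromic ones (sequences equal to their
#' own reverse complement), which self-anneal and cannot direct assembly:
#' 240 usable overhangs.
#'
#' @return character vector of 240 4-mers, sorted
#' @export
enumerate_valid_overhangs <- function() {
  g <- expand.grid(STRICT_BASES, STRICT_BASES, STRICT_BASES, STRICT_BASES,
                   stringsAsFactors = FALSE)
  all4 <- sort(paste0(g[[4]], g[[3]], g[[2]], g[[1]]))
  all4[!vapply(all4, is_palindromic_overhang, logical(1))]
}

#' Is a 4-mer palindromic (equal to its own reverse complement)?
#' @param seq 4 nt DNA string
#' @return logical scalar
#' @export
is_palindromic_overhang <- function(seq) {
  s <- as_dna_string(seq)
  identical(s, reverse_complement(s))
}

# Standard genetic code, codon -> single-letter amino acid, stop = "*".
GENETIC_CODE_TABLE <- local({
  aas <- strsplit(paste0(
    "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF"), "")[[1]]
  bases <- c("A", "C", "G", "T")
  # codons enumerated pos1-slow / pos3-fast to match the string above
  codons <- character(64); k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L; codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

#' Translate an in-frame DNA string with the standard genetic code
#'
#' @param seq strict DNA, length divisible by 3 (`nt_sequence` or string)
#' @return amino-acid string; stop codons rendered as `*`
#' @export
translate_dna <- function(seq) {
  s <- as_dna_string(seq)
  if (nchar(s) %% 3L != 0L)
    stop("sequence length (", nchar(s), ") not divisible by 3", call. = FALSE)
  if (nchar(s) == 0L) return("")
  if (!is_valid_dna(s, strict = TRUE))
    stop("translation requires a strict A/C/G/T sequence", call. = FALSE)
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  paste(GENETIC_CODE_TABLE[codons], collapse = "")
}

#' Synonymous codons for an amino acid
#' @param aa single-letter amino acid (or `*`)
#' @return character vector of codons encoding `aa`
#' @export
synonymous_codons <- function(aa) {
  names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == aa]
}

#' Extract the i-th codon (1-based) of a CDS
#' @keywords internal
codon_at <- function(seq, i) {
  substr(as_dna_string(seq), 3L * (i - 1L) + 1L, 3L * i)
}

#' Replace the i-th codon (1-based) of a CDS
#' @keywords internal
replace_codon <- function(seq, i, codon) {
  s <- as_dna_string(seq)
  paste0(substr(s, 1L, 3L * (i - 1L)), codon,
         substr(s, 3L * i + 1L, nchar(s)))
}

#' Read a coding sequence from a FASTA file
#'
#' A single-record file is read directly; a multi-record file requires `id`
#' to select the record, otherwise it is an error.
#'
#' @param path FASTA file
#' @param id optional record identifier (first whitespace-separated token of
#'   the header) to select from a multi-record file
#' @param is_cds validate CDS semantics (default `TRUE`)
#' @return an `nt_sequence`
#' @export
read_cds_fasta <- function(path, id = NULL, is_cds = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (length(set) > 1L) {
    if (is.null(id))
      stop("multi-record FASTA (", length(set),
           " records); specify `id` to select one", call. = FALSE)
    ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
    hit <- which(ids == id)
    if (length(hit) != 1L)
      stop("record '", id, "' not found (or ambiguous) in ", path, call. = FALSE)
    set <- set[hit]
  }
  nt_sequence(as.character(set[[1]]), description = names(set)[1],
              is_cds = is_cds)
}

#' Write sequences to a FASTA file
#' @param seqs named character vector (or single `nt_sequence`)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nt_sequence")) {
    nm <- attr(seqs, "description")
    seqs <- stats::setNames(as_dna_string(seqs),
                            if (nzchar(nm)) nm else "sequence")
  }
  lines <- character(0)
  for (i in seq_along(seqs)) {
    body <- gsub("(.{60})", "\\1\n", seqs[[i]])
    lines <- c(lines, paste0(">", names(seqs)[i]), strsplit(body, "\n")[[1]])
  }
  writeLines(lines, path)
  invisible(path)
}
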