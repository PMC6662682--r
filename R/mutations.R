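# Mutation specifications: 1-based amino-acid positions carrying either a
# target residue (point mutation) or a degenerate codon (site saturation).

#' Construct a mutation specification table
#'
#' @param aa_position integer vector of 1-based amino-acid positions
#' @param mode `"point"` or `"saturation"`, recycled
#' @param target for point mutations a single amino-acid letter; for
#'   saturation a degenerate codon such as `"NDT"` or `"NNK"`
#' @return data.frame with columns `aa_position`, `mode`, `target`,
#'   sorted by position
#' @export
mutation_spec <- function(aa_position, mode, target) {
  n <- length(aa_position)
  mode <- rep_len(mode, n)
  target <- rep_len(toupper(target), n)
  for (i in seq_len(n)) {
    if (!mode[i] %in% c("point", "saturation"))
      stop("mode must be 'point' or 'saturation'", call. = FALSE)
    if (mode[i] == "point") {
      if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]$", target[i]))
        stop("point mutation target must be one amino-acid letter, got '",
             target[i], "'", call. = FALSE)
    } else {
      if (nchar(target[i]) != 3L || !is_valid_dna(target[i]))
        stop("saturation target must be a 3-letter IUPAC codon, got '",
             target[i], "'", call. = FALSE)
    }
  }
  df <- data.frame(aa_position = as.integer(aa_position), mode = mode,
                   target = target)
  if (anyDuplicated(df$aa_position))
    stop("duplicate mutation positions", call. = FALSE)
  df <- df[order(df$aa_position), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Parse mutation tokens like `"D137N"` or `"137:NDT"`
#'
#' Two grammars: `<wt><pos><new>` for point mutations (the wild-type residue
#' is checked against the CDS when one is supplied to the designer) and
#' `<pos>:<codon>` for saturation with a degenerate codon.
#'
#' @param tokens character vector of mutation tokens
#' @return a mutation specification data.frame (see [mutation_spec()]); point
#'   rows carry the stated wild-type residue in an extra `wt_aa` column
#' @export
parse_mutations <- function(tokens) {
  rows <- lapply(tokens, function(tok) {
    tok <- toupper(trimws(tok))
    if (grepl("^([A-Z])(\\d+)([A-Z])$", tok)) {
      m <- regmatches(tok, regexec("^([A-Z])(\\d+)([A-Z])$", tok))[[1]]
      cbind(mutation_spec(as.integer(m[3]), "point", m[4]), wt_aa = m[2])
    } else if (grepl("^(\\d+):([A-Z]{3})$", tok)) {
      m <- regmatches(tok, regexec("^(\\d+):([A-Z]{3})$", tok))[[1]]
      cbind(mutation_spec(as.integer(m[2]), "saturation", m[3]), wt_aa = NA)
    } else {
      stop("cannot parse mutation token '", tok,
           "' (expected e.g. D137N or 137:NDT)", call. = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$aa_position), , drop = FALSE]
  if (anyDuplicated(df$aa_position))
    stop("duplicate mutation positions", call. = FALSE)
  rownames(df) <- NULL
  df
}

# Choose the codon for a point mutation: among codons of the target residue,
# minimal nucleotide distance from the old codon, then highest usage, then
# alphabetical. L69V-style single-nucleotide changes fall out naturally.
resolve_point_codon <- function(old_codon, target_aa, usage) {
  cands <- synonymous_codons(target_aa)
  if (length(cands) == 0L) stop("no codon for residue '", target_aa, "'",
                                call. = FALSE)
  dist <- vapply(cands, function(cd) {
    sum(strsplit(cd, "")[[1]] != strsplit(old_codon, "")[[1]])
  }, integer(1))
  fr <- vapply(cands, function(cd) usage_fraction(usage, cd), numeric(1))
  cands[order(dist, -fr, cands)][1]
}

# Validate mutations against a CDS and resolve concrete replacement codons.
# Returns the spec with wt_codon/new_codon columns; saturation rows keep the
# degenerate codon in new_codon.
resolve_mutations <- function(seq, mutations, usage,
                              allow_terminal = FALSE) {
  s <- as_dna_string(seq)
  n_codons <- nchar(s) %/% 3L
  if (nrow(mutations) == 0L) {
    return(cbind(mutations, wt_codon = character(0), new_codon = character(0)))
  }
  lo <- if (allow_terminal) 1L else 2L
  hi <- if (allow_terminal) n_codons else n_codons - 1L
  bad <- mutations$aa_position < lo | mutations$aa_position > hi
  if (any(bad))
    stop("mutation position(s) ", paste(mutations$aa_position[bad],
         collapse = ", "), " outside mutable range [", lo, ", ", hi,
         "] (start/stop codons are not mutable by default)", call. = FALSE)
  mutations$wt_codon <- vapply(mutations$aa_position,
                               function(p) codon_at(s, p), character(1))
  if ("wt_aa" %in% names(mutations)) {
    for (i in seq_len(nrow(mutations))) {
      stated <- mutations$wt_aa[i]
      if (!is.na(stated) &&
          stated != GENETIC_CODE_TABLE[[mutations$wt_codon[i]]])
        stop("mutation ", stated, mutations$aa_position[i],
             ": CDS has ", GENETIC_CODE_TABLE[[mutations$wt_codon[i]]],
             " at position ", mutations$aa_position[i], call. = FALSE)
    }
  }
  mutations$new_codon <- vapply(seq_len(nrow(mutations)), function(i) {
    if (mutations$mode[i] == "point")
      resolve_point_codon(mutations$wt_codon[i], mutations$target[i], usage)
    else mutations$target[i]
  }, character(1))
  mutations
}

# Apply resolved mutations to a template; degenerate codons go in verbatim.
apply_mutations <- function(seq, resolved) {
  s <- as_dna_string(seq)
  for (i in seq_len(nrow(resolved)))
    s <- replace_codon(s, resolved$aa_position[i], resolved$new_codon[i])
  s
}
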