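# Organism codon-usage tables (bundled, Kazusa-style relative synonymous
# fractions). Used to prefer frequent codons when proposing silent fixes.

CODON_USAGE_ORGANISMS <- c("e_coli", "s_cerevisiae", "a_thaliana")

usage_env <- new.env(parent = emptyenv())

#' Load a bundled codon usage table
#'
#' Returns relative synonymous codon usage for the organism: for every amino
#' acid the fractions of its synonymous codons sum to 1. Tables are bundled
#' as CSV under `inst/extdata/` (see the data README there for provenance)
#' and renormalised per amino acid on load.
#'
#' @param organism `"e_coli"` (default), `"s_cerevisiae"` or `"a_thaliana"`
#' @return object of class `codon_usage`: a data.frame with columns `codon`,
#'   `aa`, `fraction`, plus an `organism` attribute
#' @export
codon_usage <- function(organism = c("e_coli", "s_cerevisiae", "a_thaliana")) {
  organism <- match.arg(organism)
  if (!is.null(usage_env[[organism]])) return(usage_env[[organism]])
  path <- system.file("extdata",
                      paste0("codon_usage_", organism, ".csv"),
                      package = "gatemut", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 64L,
            identical(sort(df$codon), sort(names(GENETIC_CODE_TABLE))))
  if (!identical(stats::setNames(df$aa, df$codon)[names(GENETIC_CODE_TABLE)],
                 GENETIC_CODE_TABLE))
    stop("codon usage table disagrees with the standard genetic code",
         call. = FALSE)
  for (a in unique(df$aa)) {
    i <- df$aa == a
    df$fraction[i] <- df$fraction[i] / sum(df$fraction[i])
  }
  out <- structure(df, class = c("codon_usage", "data.frame"),
                   organism = organism)
  usage_env[[organism]] <- out
  out
}

#' Relative usage fraction of one codon
#' @param usage a `codon_usage` table
#' @param codon strict codon
#' @return numeric fraction in (0, 1]
#' @export
usage_fraction <- function(usage, codon) {
  i <- match(toupper(codon), usage$codon)
  if (is.na(i)) stop("unknown codon '", codon, "'", call. = FALSE)
  usage$fraction[i]
}

#' Most frequent codon for an amino acid in an organism
#' @param usage a `codon_usage` table
#' @param aa single-letter amino acid
#' @return a strict codon
#' @export
preferred_codon <- function(usage, aa) {
  rows <- usage[usage$aa == aa, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown amino acid '", aa, "'", call. = FALSE)
  rows$codon[order(-rows$fraction, rows$codon)][1]
}
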