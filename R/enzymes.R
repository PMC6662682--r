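# Type IIS enzyme and vector constants.
#
# Cut geometry (REBASE): BsaI GGTCTC(1/5), BbsI GAAGAC(2/6) -- the top strand
# is cut `spacer_len` nt downstream of the recognition end, the bottom strand
# 4 nt further, leaving a 4 nt 5' overhang. Both recognition sequences are
# non-palindromic, so orientation matters and both strands must be scanned.

#' Construct a type IIS enzyme definition
#'
#' @param name enzyme name
#' @param recognition recognition sequence (top strand, 5' to 3')
#' @param spacer_len nt between the recognition end and the top-strand cut
#' @param overhang_len length of the 5' overhang left behind (always 4 here)
#' @return object of class `tiis_enzyme`
#' @export
tiis_enzyme <- function(name, recognition, spacer_len, overhang_len = 4L) {
  stopifnot(is_valid_dna(recognition, strict = TRUE), overhang_len == 4L,
            spacer_len >= 0L)
  if (identical(recognition, reverse_complement(recognition)))
    stop("type IIS recognition sequences must be non-palindromic", call. = FALSE)
  structure(list(name = name, recognition = toupper(recognition),
                 spacer_len = as.integer(spacer_len),
                 overhang_len = as.integer(overhang_len)),
            class = "tiis_enzyme")
}

#' @export
print.tiis_enzyme <- function(x, ...) {
  cat(sprintf("<tiis_enzyme> %s  %s(%d/%d)\n", x$name, x$recognition,
              x$spacer_len, x$spacer_len + x$overhang_len))
  invisible(x)
}

#' BsaI: GGTCTC(1/5), 4 nt 5' overhang
#' @export
BSAI <- tiis_enzyme("BsaI", "GGTCTC", 1L)

#' BbsI: GAAGAC(2/6), 4 nt 5' overhang
#' @export
BBSI <- tiis_enzyme("BbsI", "GAAGAC", 2L)

#' Look up a bundled enzyme by name
#' @param name `"BsaI"` or `"BbsI"`
#' @return a `tiis_enzyme`
#' @export
get_enzyme <- function(name) {
  switch(name,
         BsaI = BSAI,
         BbsI = BBSI,
         stop("unknown enzyme '", name, "' (supported: BsaI, BbsI)",
              call. = FALSE))
}

#' Construct a destination-vector specification
#'
#' `five_template_overlap` records how many of the 4 overhang bases coincide
#' with the start of the insert CDS: the expression vector's AATG overhang
#' contains the ATG start codon (one vector-derived A precedes it), whereas
#' the cloning vector's CTCA/CGAG overhangs are pure vector sequence.
#'
#' @param name vector name
#' @param enzyme the `tiis_enzyme` that releases the cloning site
#' @param five_prime_overhang,three_prime_overhang fixed 4 bp vector overhangs
#' @param five_template_overlap nt of the 5' overhang shared with the CDS
#' @return object of class `vector_spec`
#' @export
vector_spec <- function(name, enzyme, five_prime_overhang,
                        three_prime_overhang, five_template_overlap = 0L) {
  for (oh in c(five_prime_overhang, three_prime_overhang)) {
    stopifnot(nchar(oh) == 4L, is_valid_dna(oh, strict = TRUE))
    if (is_palindromic_overhang(oh))
      stop("vector overhang ", oh, " is palindromic", call. = FALSE)
  }
  structure(list(name = name, enzyme = enzyme,
                 five_prime_overhang = toupper(five_prime_overhang),
                 three_prime_overhang = toupper(three_prime_overhang),
                 five_template_overlap = as.integer(five_template_overlap)),
            class = "vector_spec")
}

#' @export
print.vector_spec <- function(x, ...) {
  cat(sprintf("<vector_spec> %s  enzyme %s  overhangs %s / %s\n",
              x$name, x$enzyme$name, x$five_prime_overhang,
              x$three_prime_overhang))
  invisible(x)
}

#' Universal level 0 cloning vector pAGM9121 (BbsI, overhangs CTCA/CGAG)
#' @export
PAGM9121 <- vector_spec("pAGM9121", BBSI, "CTCA", "CGAG", 0L)

#' Level 2 E. coli expression vector pAGM22082_CRed (BsaI, overhangs
#' AATG/GCTT; AATG supplies the start codon in frame with the vector's
#' N-terminal linker)
#' @export
PAGM22082_CRED <- vector_spec("pAGM22082_CRed", BSAI, "AATG", "GCTT", 3L)

#' Look up a bundled vector by name
#' @param name `"pAGM9121"` or `"pAGM22082_CRed"`
#' @return a `vector_spec`
#' @export
get_vector <- function(name) {
  switch(name,
         pAGM9121 = PAGM9121,
         pAGM22082_CRed = PAGM22082_CRED,
         stop("unknown vector '", name,
              "' (supported: pAGM9121, pAGM22082_CRed)", call. = FALSE))
}
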