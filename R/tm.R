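# Nearest-neighbor melting temperature (SantaLucia 1998 unified parameters).
# Conditions are fixed package-wide: 50 mM monovalent salt, 500 nM total
# oligonucleotide, entropy-based salt correction (0.368 * (N-1) * ln[Na+]).

# Unified NN parameters: dH in kcal/mol, dS in cal/(mol K).
# The 10 unique stacks; complementary stacks share values.
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# terminal initiation terms
INIT_AT <- c(dh = 2.3, ds = 4.1)
INIT_GC <- c(dh = 0.1, ds = -2.8)
SYM_DS <- -1.4  # self-complementary duplex entropy penalty

GAS_CONSTANT <- 1.987  # cal/(mol K)

#' Nearest-neighbor melting temperature of a primer binding region
#'
#' Unified nearest-neighbor thermodynamics (duplex initiation terms per
#' terminal A/T or G/C, self-complementarity symmetry correction) at 50 mM
#' monovalent salt and 500 nM total oligonucleotide. The salt correction is
#' applied to the entropy term, 0.368 (N-1) ln[Na+]. Deterministic; no
#' mismatch or dangling-end terms.
#'
#' @param binding strict DNA string, length >= 8
#' @param Na monovalent cation concentration, mol/L (default 0.05)
#' @param oligo_conc total single-strand concentration, mol/L (default 5e-7)
#' @return melting temperature in degrees Celsius
#' @export
melting_temperature <- function(binding, Na = 0.05, oligo_conc = 5e-7) {
  s <- as_dna_string(binding)
  if (!is_valid_dna(s, strict = TRUE))
    stop("Tm requires a strict A/C/G/T binding region (no degenerate bases)",
         call. = FALSE)
  n <- nchar(s)
  if (n < 8L) stop("binding region too short for nearest-neighbor Tm (", n,
                   " < 8 nt)", call. = FALSE)
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  stacks <- paste0(b[-n], b[-1L])
  dh <- sum(NN_DH[stacks])
  ds <- sum(NN_DS[stacks])
  for (term in c(b[1L], b[n])) {
    if (term %in% c("A", "T")) {
      dh <- dh + INIT_AT[["dh"]]; ds <- ds + INIT_AT[["ds"]]
    } else {
      dh <- dh + INIT_GC[["dh"]]; ds <- ds + INIT_GC[["ds"]]
    }
  }
  selfcomp <- identical(s, reverse_complement(s))
  if (selfcomp) ds <- ds + SYM_DS
  # duplex concentration term: CT/4 for two different strands at equal
  # concentration, CT/2 for a self-complementary oligo
  k <- if (selfcomp) oligo_conc / 2 else oligo_conc / 4
  ds <- ds + 0.368 * (n - 1L) * log(Na)
  1000 * dh / (ds + GAS_CONSTANT * log(k)) - 273.15
}

#' Grow a primer binding region from an anchor until it reaches a target Tm
#'
#' For `direction = "forward"` the region grows 3' from `anchor` (0-based,
#' inclusive start in template coordinates); for `"reverse"` it grows 5' from
#' `anchor` (exclusive end), and the returned primer-oriented sequence is the
#' reverse complement of the template window. The region returned is the
#' shortest one with `Tm >= target_tm`, subject to length in
#' `[min_len, max_len]`; if the cap is reached below target the capped region
#' is returned with `low_tm = TRUE`.
#'
#' @param template strict DNA template (plus strand)
#' @param anchor 0-based template coordinate (start for forward, end for
#'   reverse)
#' @param direction `"forward"` or `"reverse"`
#' @param target_tm target melting temperature, degrees C (default 60)
#' @param min_len,max_len length bounds in nt (defaults 12 and 45)
#' @return list: `sequence` (primer-oriented 5'->3'), `region` (template
#'   window, plus strand), `start`, `end` (0-based half-open template
#'   coordinates), `tm`, `low_tm`
#' @export
extend_binding <- function(template, anchor, direction = c("forward", "reverse"),
                           target_tm = 60, min_len = 12L, max_len = 45L) {
  direction <- match.arg(direction)
  s <- as_dna_string(template)
  n <- nchar(s)
  anchor <- as.integer(anchor)
  if (anchor < 0L || anchor > n)
    stop("anchor ", anchor, " outside template [0, ", n, "]", call. = FALSE)
  avail <- if (direction == "forward") n - anchor else anchor
  if (avail < min_len)
    stop("template exhausted: only ", avail, " nt available ",
         direction, " of anchor ", anchor, " (need >= ", min_len, ")",
         call. = FALSE)
  len <- min_len
  repeat {
    region <- if (direction == "forward")
      substr(s, anchor + 1L, anchor + len)
    else substr(s, anchor - len + 1L, anchor)
    tm <- melting_temperature(region)
    if (tm >= target_tm || len >= max_len || len >= avail) break
    len <- len + 1L
  }
  list(sequence = if (direction == "forward") region
                  else reverse_complement(region),
       region = region,
       start = if (direction == "forward") anchor else anchor - len,
       end = if (direction == "forward") anchor + len else anchor,
       tm = tm,
       low_tm = tm < target_tm)
}
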