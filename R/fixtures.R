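# Synthetic data generation: random CDSs with optionally planted type IIS
# sites, and synthetic pooled-library ABIF chromatograms with known codon
# mixtures. Everything is deterministic for a fixed seed, so the whole
# suite is testable without any external dataset.

# run expr with a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  force(expr)
}

SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

#' Generate a random CDS free of BsaI/BbsI sites
#'
#' Uniformly random sense codons between an ATG start and a TAA stop.
#' Codons overlapping any type IIS recognition site are resampled until the
#' sequence is clean, so the result is always directly clonable.
#'
#' @param n_codons total codon count including start and stop (>= 20)
#' @param seed RNG seed (deterministic output; same seed, same CDS)
#' @return an `nt_sequence` with `is_cds = TRUE`
#' @export
synth_cds <- function(n_codons = 250L, seed = 1L) {
  stopifnot(n_codons >= 20L)
  with_seed(seed, {
    codons <- c("ATG", sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                "TAA")
    s <- paste(codons, collapse = "")
    for (tries in 1:200) {
      hits <- scan_sites(s, list(BSAI, BBSI))
      if (nrow(hits) == 0L) break
      for (ci in hits$overlapped_codons[[1]]) {
        if (ci <= 1L || ci >= n_codons) next
        s <- replace_codon(s, ci, sample(SENSE_CODONS, 1L))
      }
    }
    if (nrow(scan_sites(s, list(BSAI, BBSI))) > 0L)
      stop("could not generate a site-free CDS", call. = FALSE)
    nt_sequence(s, description = sprintf("synthetic CDS %d codons seed %d",
                                         n_codons, seed), is_cds = TRUE)
  })
}

#' Plant a type IIS recognition site at a given offset
#'
#' Overwrites the bases at `offset` (0-based) with the enzyme's recognition
#' sequence (or its reverse complement for the minus strand). Errors if the
#' edit would damage the start/stop codons or create an internal stop.
#'
#' @param seq a CDS
#' @param enzyme a `tiis_enzyme`
#' @param offset 0-based plus-strand offset for the site
#' @param strand `"+"` or `"-"`
#' @return the edited `nt_sequence` (still a valid CDS; the encoded protein
#'   generally changes -- this is a test fixture, not a silent edit)
#' @export
plant_site <- function(seq, enzyme, offset, strand = "+") {
  s <- as_dna_string(seq)
  pat <- if (strand == "+") enzyme$recognition
         else reverse_complement(enzyme$recognition)
  len <- nchar(pat)
  if (offset < 3L || offset + len > nchar(s) - 3L)
    stop("site at offset ", offset, " would overlap the start or stop codon",
         call. = FALSE)
  edited <- paste0(substr(s, 1L, offset), pat,
                   substr(s, offset + len + 1L, nchar(s)))
  aa <- translate_dna(edited)
  if (grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE))
    stop("planting at offset ", offset, " creates an internal stop codon",
         call. = FALSE)
  nt_sequence(edited, description = attr(seq, "description"), is_cds = TRUE)
}

#' Generate a CDS with a known number of planted type IIS sites
#'
#' Starts from a clean [synth_cds()] and plants sites at random in-frame
#' compatible offsets, retrying until exactly the requested sites (and no
#' accidental extras) are present and, optionally, every site is removable
#' by a silent single-codon substitution.
#'
#' @param n_codons CDS length in codons
#' @param n_sites number of sites to plant
#' @param enzymes enzymes to draw from (default BsaI and BbsI)
#' @param seed RNG seed
#' @param require_fixable retry until [domesticate()] succeeds (default TRUE)
#' @return list: `sequence` (the planted `nt_sequence`), `sites` (the
#'   [scan_sites()] table of the planted sites)
#' @export
synth_cds_with_sites <- function(n_codons = 250L, n_sites = 1L,
                                 enzymes = list(BSAI, BBSI), seed = 1L,
                                 require_fixable = TRUE) {
  with_seed(seed, {
    for (attempt in 1:100) {
      base <- synth_cds(n_codons, seed = sample.int(1e6, 1L))
      s <- base
      ok <- TRUE
      # spread sites over disjoint windows so they cannot collide
      slots <- floor(seq(6L, 3L * n_codons - 12L, length.out = n_sites + 1L))
      for (i in seq_len(n_sites)) {
        enz <- enzymes[[1L + (i - 1L) %% length(enzymes)]]
        strand <- sample(c("+", "-"), 1L)
        off <- sample(seq(slots[i], slots[i + 1L] - 7L), 1L)
        s <- tryCatch(plant_site(s, enz, off, strand),
                      error = function(e) NULL)
        if (is.null(s)) { ok <- FALSE; break }
      }
      if (!ok) next
      hits <- scan_sites(s, enzymes)
      if (nrow(hits) != n_sites) next
      if (require_fixable) {
        fixed <- tryCatch(domesticate(s), error = function(e) NULL)
        if (is.null(fixed)) next
      }
      return(list(sequence = s, sites = hits))
    }
    stop("could not construct a planted-site fixture", call. = FALSE)
  })
}

#' Generate a random saturation mutation spec for a CDS
#'
#' @param seq the CDS
#' @param n_sites number of saturation sites (1-5 typical)
#' @param codon degenerate codon to use (default NDT)
#' @param seed RNG seed
#' @param min_gap_codons minimal spacing between drawn positions (default 40,
#'   so that each site becomes its own cluster and fragments stay above the
#'   default minimal length)
#' @return a mutation spec data.frame
#' @export
synth_mutations <- function(seq, n_sites = 3L, codon = "NDT", seed = 1L,
                            min_gap_codons = 40L) {
  n_codons <- nchar(as_dna_string(seq)) %/% 3L
  with_seed(seed, {
    # keep >= 40 codons clear of both ends so every fragment stays above
    # the default 100 nt minimum even after overhang-window shifts
    lo <- 40L
    hi <- n_codons - 40L
    slack <- hi - lo - (n_sites - 1L) * min_gap_codons
    if (slack < 0L)
      stop("cannot place ", n_sites, " sites with gap >= ", min_gap_codons,
           " in ", n_codons, " codons", call. = FALSE)
    # allocate the slack over the n_sites + 1 gaps, then lay positions down
    extra <- as.vector(stats::rmultinom(1L, slack, rep(1, n_sites + 1L)))
    pos <- lo + cumsum(extra[seq_len(n_sites)]) +
      (seq_len(n_sites) - 1L) * min_gap_codons
    mutation_spec(pos, "saturation", codon)
  })
}

# per-position ideal base probabilities of a pooled library read;
# `perturb` multiplies each variant codon's weight by log-normal noise
# (per-variant amplification bias), the dominant noise source in a pool
pool_probabilities <- function(reference, weights = NULL, perturb = 0) {
  ref_b <- strsplit(as_dna_string(reference), "")[[1]]
  n <- length(ref_b)
  probs <- matrix(0, n, 4L, dimnames = list(NULL, STRICT_BASES))
  deg_codons <- sort(unique((which(!ref_b %in% STRICT_BASES) - 1L) %/% 3L + 1L))
  for (i in seq_len(n)) {
    ci <- (i - 1L) %/% 3L + 1L
    if (ref_b[i] %in% STRICT_BASES && !(ci %in% deg_codons)) {
      probs[i, ref_b[i]] <- 1
    }
  }
  for (ci in deg_codons) {
    cod <- paste(ref_b[3L * (ci - 1L) + 1:3], collapse = "")
    w <- if (!is.null(weights) && !is.null(weights[[as.character(ci)]])) {
      weights[[as.character(ci)]]
    } else {
      ex <- expand_degenerate_codon(cod)
      stats::setNames(rep(1 / length(ex), length(ex)), ex)
    }
    w <- w / sum(w)
    if (perturb > 0)
      w <- w * exp(stats::rnorm(length(w), 0, perturb))
    w <- w / sum(w)
    for (j in 1:3) {
      i <- 3L * (ci - 1L) + j
      probs[i, ] <- 0
      for (cd in names(w)) {
        b <- substr(cd, j, j)
        probs[i, b] <- probs[i, b] + w[[cd]]
      }
    }
  }
  probs
}

#' Write a synthetic pooled-library ABIF chromatogram
#'
#' Emulates Sanger sequencing of a plasmid pool built from a saturation
#' design: the trace is the weighted sum of the per-variant ideal traces,
#' with each variant codon's contribution multiplied by log-normal noise of
#' sigma `noise_sd` (per-variant amplification bias, the mechanism behind
#' the base-ratio skews seen in real pooled reads). Channel intensities at
#' each call are proportional to the resulting base frequencies; basecalls
#' are the per-position channel maxima. One scan per call; the file
#' round-trips through [read_abif()].
#'
#' @param reference the designed insert: mutated template with degenerate
#'   codes at the randomized codons
#' @param path output `.ab1` path
#' @param weights optional named list: codon index -> named weight vector
#'   over strict codons of the pool at that site
#' @param noise_sd log-normal sigma (default 0.1; 0 for noise-free)
#' @param seed RNG seed (default 42)
#' @param amplitude mean channel intensity of a pure base (default 1000)
#' @param direction write the read `"forward"` or `"reverse"` (reverse
#'   reads are the reverse complement, channels swapped accordingly)
#' @return invisibly, a list: `path`, `truth` (data.frame of ideal
#'   proportions per randomized position: `codon_index`, `offset`,
#'   `A`, `C`, `G`, `T`)
#' @export
synth_abif_pool <- function(reference, path, weights = NULL, noise_sd = 0.1,
                            seed = 42L, amplitude = 1000,
                            direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  ref <- as_dna_string(reference)
  with_seed(seed, {
    probs <- pool_probabilities(ref, weights, perturb = noise_sd)
    n <- nrow(probs)
    inten <- probs * amplitude
    basecalls <- apply(inten, 1L, function(r) STRICT_BASES[which.max(r)])
    if (direction == "reverse") {
      inten <- inten[n:1, c("T", "G", "C", "A"), drop = FALSE]
      colnames(inten) <- STRICT_BASES
      basecalls <- strsplit(reverse_complement(paste(basecalls,
                                                     collapse = "")), "")[[1]]
    }
    write_abif(inten[, c("G", "A", "T", "C"), drop = FALSE],
               paste(basecalls, collapse = ""),
               peak_locations = 0:(n - 1L), path = path, fwo = "GATC")
  })
  probs <- pool_probabilities(ref, weights)  # ideal, unperturbed truth
  ref_b <- strsplit(ref, "")[[1]]
  deg <- sort(unique((which(!ref_b %in% STRICT_BASES) - 1L) %/% 3L + 1L))
  truth <- do.call(rbind, lapply(deg, function(ci) {
    do.call(rbind, lapply(1:3, function(j) {
      i <- 3L * (ci - 1L) + j
      data.frame(codon_index = ci, offset = j,
                 A = probs[i, "A"], C = probs[i, "C"],
                 G = probs[i, "G"], T = probs[i, "T"])
    }))
  }))
  invisible(list(path = path, truth = truth))
}
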