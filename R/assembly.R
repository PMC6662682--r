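# In-silico Golden Gate oracle: simulate PCR product formation, type IIS
# digestion and overhang-directed ligation, and verify that a design
# reassembles the intended (possibly degenerate) CDS seamlessly.
#
# The simulator is combinatorial and deterministic: double-stranded DNA is
# represented by its plus strand, degenerate bases are carried symbolically,
# and no ligation kinetics or mismatch ligation is modelled.

#' Simulate PCR with two structured primers on a template
#'
#' Both binding regions must match the template exactly (forward on the plus
#' strand, reverse on the minus strand) and the forward anchor must lie 5'
#' of the reverse anchor. The product is the forward primer, the intervening
#' template, and the reverse complement of the reverse primer; degenerate
#' positions in mutagenic inserts are preserved.
#'
#' @param template strict DNA (plus strand)
#' @param fwd,rev `gg_primer` objects (one forward, one reverse)
#' @return the product DNA string (plus strand)
#' @export
simulate_pcr <- function(template, fwd, rev) {
  s <- as_dna_string(template)
  if (!identical(fwd$direction, "forward") ||
      !identical(rev$direction, "reverse"))
    stop("primer does not anneal: need one forward and one reverse primer ",
         "in this orientation", call. = FALSE)
  f_site <- substr(s, fwd$binding_start + 1L, fwd$binding_end)
  r_site <- substr(s, rev$binding_start + 1L, rev$binding_end)
  if (!identical(f_site, fwd$binding))
    stop("primer does not anneal: forward binding region mismatches the ",
         "template at ", fwd$binding_start, call. = FALSE)
  if (!identical(r_site, rev$binding_region))
    stop("primer does not anneal: reverse binding region mismatches the ",
         "template at ", rev$binding_start, call. = FALSE)
  if (fwd$binding_start >= rev$binding_start ||
      fwd$binding_end > rev$binding_start)
    stop("primer does not anneal: inverted or overlapping primer pair",
         call. = FALSE)
  paste0(fwd$full,
         substr(s, fwd$binding_end + 1L, rev$binding_start),
         reverse_complement(rev$full))
}

#' Digest a PCR product with a type IIS enzyme
#'
#' Expects exactly one recognition site near each end, facing inward (the
#' plus-strand site on the left, the minus-strand site on the right). Cuts
#' at the enzyme's offset and returns the interior fragment with its two
#' 4 nt overhangs exposed; recognition site and spacer are liberated with
#' the outer pieces. Sites are matched literally: a site that only some
#' expansions of a degenerate insert would form is a library-bias hazard
#' (those members are re-cut and depleted during the one-pot reaction),
#' not a digestion failure.
#'
#' @param product DNA string (may contain degenerate codes in inserts)
#' @param enzyme a `tiis_enzyme`
#' @return object of class `digested_fragment`: `core`, `left_overhang`,
#'   `right_overhang` (plus-strand representation)
#' @export
digest <- function(product, enzyme) {
  p <- as_dna_string(product)
  rec <- enzyme$recognition
  plus <- find_certain(rec, p)
  minus <- find_certain(reverse_complement(rec), p)
  if (length(plus) != 1L || length(minus) != 1L)
    stop("internal site: expected exactly one ", enzyme$name,
         " site per strand, found ", length(plus), " (+) and ",
         length(minus), " (-)", call. = FALSE)
  if (plus > minus)
    stop("orientation: ", enzyme$name,
         " sites face outward; cannot release an insert", call. = FALSE)
  cut_left <- plus + nchar(rec) + enzyme$spacer_len
  cut_right <- minus - enzyme$spacer_len - enzyme$overhang_len
  if (cut_right < cut_left + enzyme$overhang_len)
    stop("orientation: cut sites overlap; no interior fragment", call. = FALSE)
  structure(list(
    core = substr(p, cut_left + enzyme$overhang_len + 1L, cut_right),
    left_overhang = substr(p, cut_left + 1L, cut_left + enzyme$overhang_len),
    right_overhang = substr(p, cut_right + 1L,
                            cut_right + enzyme$overhang_len)),
    class = "digested_fragment")
}

#' Ligate digested fragments into the acceptor vector
#'
#' Joins fragments wherever the right overhang of one equals the left
#' overhang of the next, starting from the vector's 5' overhang and ending
#' at its 3' overhang. The chain must be unique: duplicated overhangs give
#' an "ambiguous assembly" error, a missing link "unassemblable".
#'
#' @param fragments list of `digested_fragment`
#' @param vector a `vector_spec`
#' @return object of class `assembly_outcome`: `assembled_insert` (between
#'   and including the vector overhangs), `assembled_cds` (vector overhang
#'   bases stripped; for the expression vector the AATG overhang contributes
#'   the start codon), `is_seamless` (NA until [verify_design()] checks it),
#'   `mutated_codon_indices`
#' @export
ligate <- function(fragments, vector) {
  if (length(fragments) == 0L)
    stop("unassemblable: empty fragment set", call. = FALSE)
  lefts <- vapply(fragments, `[[`, character(1), "left_overhang")
  rights <- vapply(fragments, `[[`, character(1), "right_overhang")
  if (anyDuplicated(lefts) || anyDuplicated(rights))
    stop("ambiguous assembly: duplicated overhangs among fragments",
         call. = FALSE)
  current <- vector$five_prime_overhang
  used <- rep(FALSE, length(fragments))
  pieces <- current
  repeat {
    nxt <- which(!used & lefts == current)
    if (length(nxt) > 1L)
      stop("ambiguous assembly: overhang ", current, " matches ",
           length(nxt), " fragments", call. = FALSE)
    if (length(nxt) == 0L) {
      if (current == vector$three_prime_overhang && all(used)) break
      stop("unassemblable: no fragment continues from overhang ", current,
           if (!all(used)) paste0(" (", sum(!used), " fragment(s) unused)")
           else "", call. = FALSE)
    }
    used[nxt] <- TRUE
    pieces <- c(pieces, fragments[[nxt]]$core, rights[nxt])
    current <- rights[nxt]
  }
  insert <- paste(pieces, collapse = "")
  # strip vector-only overhang bases to recover the CDS: the expression
  # vector's AATG overhang overlaps the start codon by 3 nt
  lead <- 4L - vector$five_template_overlap
  cds <- substr(insert, lead + 1L, nchar(insert) - 4L)
  structure(list(assembled_insert = insert, assembled_cds = cds,
                 is_seamless = NA, mutated_codon_indices = integer(0)),
            class = "assembly_outcome")
}

#' @export
print.assembly_outcome <- function(x, ...) {
  cat(sprintf("<assembly_outcome> %d nt insert, seamless: %s, mutated codons: %s\n",
              nchar(x$assembled_insert), as.character(x$is_seamless),
              if (length(x$mutated_codon_indices))
                paste(x$mutated_codon_indices, collapse = ", ") else "none"))
  invisible(x)
}

#' Verify a design end to end by simulated assembly
#'
#' Runs PCR, digestion and ligation for every fragment of the design,
#' asserts that the assembled insert reconstructs the mutated template
#' exactly (seamless, no frameshift), that substitutions are confined to
#' the specified codons, that the insert retains no recognition site of the
#' assembly enzyme, and -- for saturation designs -- that sampled strict
#' expansions of every degenerate codon give an in-frame CDS carrying the
#' sampled codon.
#'
#' @param seq the wild-type template CDS the primers anneal to
#' @param mutations the mutation spec used for the design (positions are
#'   cross-checked against the outcome)
#' @param result a `design_result`
#' @param n_samples strict expansions sampled per degenerate codon (default 3)
#' @param seed RNG seed for expansion sampling (default 17)
#' @return an `assembly_outcome` with `is_seamless` and
#'   `mutated_codon_indices` filled in
#' @export
verify_design <- function(seq, mutations, result, n_samples = 3L, seed = 17L) {
  stopifnot(inherits(result, "design_result"))
  wt <- as_dna_string(seq)
  mt <- result$plan$mutated_template
  enzyme <- result$vector$enzyme
  K <- nrow(result$plan$fragments)
  digested <- vector("list", K)
  for (k in seq_len(K)) {
    digested[[k]] <- tryCatch({
      prod <- simulate_pcr(wt, result$primers[[2L * k - 1L]],
                           result$primers[[2L * k]])
      digest(prod, enzyme)
    }, error = function(e) {
      stop("fragment ", k, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  outcome <- ligate(digested, result$vector)
  cds <- outcome$assembled_cds

  seamless <- identical(nchar(cds), nchar(wt)) && identical(cds, mt)
  # substitution locality: differences from wild type only inside the
  # specified codon windows
  diffs <- which(strsplit(cds, "")[[1]] != strsplit(wt, "")[[1]])
  mut_codons <- sort(unique((diffs - 1L) %/% 3L + 1L))
  specified <- sort(result$plan$mutations$aa_position)
  if (!all(mut_codons %in% specified)) seamless <- FALSE
  # every user-requested position must be represented in the design
  if (!is.null(mutations) && nrow(mutations) > 0L &&
      !all(mutations$aa_position %in% specified)) seamless <- FALSE
  # liberation: the designed insert carries no site of the assembly enzyme
  # outside the degenerate positions (literal match; variant-dependent
  # sites inside randomized codons are a depletion hazard, not a failure)
  if (length(find_certain(enzyme$recognition, cds)) > 0L ||
      length(find_certain(reverse_complement(enzyme$recognition),
                          cds)) > 0L)
    seamless <- FALSE
  # saturation designs: sampling any strict expansion of every degenerate
  # codon must give an in-frame CDS with the sampled codon at the site
  sat <- result$plan$mutations[result$plan$mutations$mode == "saturation", ,
                               drop = FALSE]
  if (nrow(sat) > 0L) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    for (rep in seq_len(n_samples)) {
      inst <- cds
      for (i in seq_len(nrow(sat))) {
        pos <- sat$aa_position[i]
        exp_set <- expand_degenerate_codon(sat$new_codon[i])
        pick <- sample(exp_set, 1L)
        inst <- replace_codon(inst, pos, pick)
        if (!identical(codon_at(inst, pos), pick)) seamless <- FALSE
      }
      if (nchar(inst) %% 3L != 0L) seamless <- FALSE
      if (!is_valid_dna(inst, strict = TRUE)) seamless <- FALSE
    }
  }
  outcome$is_seamless <- seamless
  outcome$mutated_codon_indices <- mut_codons
  outcome
}
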