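# The design engine: split a CDS into fragments at mutation clusters, pick
# valid 4 bp junction overhangs, and emit structured mutagenic primers
# (padding | recognition | spacer | overhang | mutagenic insert | binding)
# with Tm-balanced binding regions.
#
# Conventions (documented in the methods vignette):
#  * mutagenic codons ride on the FORWARD primer of the downstream fragment;
#  * each junction sits immediately 5' of its cluster's first mutated codon,
#    shifted up to `max_overhang_shift` nt further 5' when needed to find a
#    valid overhang (intervening template bases are carried verbatim in the
#    mutagenic insert);
#  * fragment boundaries coincide with junction-overhang window starts, so
#    fragments tile the CDS.

#' Greedy left-to-right clustering of mutation sites
#'
#' A mutation joins the current cluster iff the nucleotide span from the
#' cluster's first mutated codon to the end of this codon is at most
#' `max_cluster_span_nt`. Each cluster becomes one fragment junction, so the
#' fragment count is always `length(clusters) + 1`.
#'
#' @param positions sorted distinct 1-based amino-acid positions (or a
#'   mutation spec data.frame)
#' @param max_cluster_span_nt maximal nt span of one cluster (default 45,
#'   which keeps total primer length within ordinary synthesis limits)
#' @return list of integer vectors of positions, in order
#' @export
cluster_mutations <- function(positions, max_cluster_span_nt = 45L) {
  if (is.data.frame(positions)) positions <- positions$aa_position
  positions <- as.integer(positions)
  if (length(positions) == 0L) return(list())
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be sorted and distinct", call. = FALSE)
  clusters <- list()
  current <- positions[1]
  for (p in positions[-1]) {
    span <- (p - current[1] + 1L) * 3L
    if (span <= max_cluster_span_nt) {
      current <- c(current, p)
    } else {
      clusters[[length(clusters) + 1L]] <- current
      current <- p
    }
  }
  clusters[[length(clusters) + 1L]] <- current
  clusters
}

# Is `w` usable as a new overhang given the set already in use? Overhangs
# must be non-palindromic, pairwise distinct, and no overhang may equal the
# reverse complement of another (both orientations are present in the pot).
overhang_ok <- function(w, used) {
  nchar(w) == 4L && is_valid_dna(w, strict = TRUE) &&
    !is_palindromic_overhang(w) &&
    !(w %in% used) && !(reverse_complement(w) %in% used)
}

#' Plan the fragmentation of a CDS around mutation clusters
#'
#' Clusters the mutation sites, places one junction immediately 5' of each
#' cluster's first mutated codon, and chooses the junction overhang as the
#' 4 nt template window ending at the junction, shifted up to
#' `max_overhang_shift` nt further 5' until the overhang is valid against
#' all others in the design (non-palindromic, distinct, non-complementary).
#' Fragment boundaries are the overhang window starts; the first fragment
#' starts at 0 and the last ends at the CDS end, so fragments tile the CDS.
#'
#' @param seq wild-type CDS (`nt_sequence`, `is_cds = TRUE` recommended)
#' @param mutations mutation spec data.frame (see [mutation_spec()];
#'   may be empty for wild-type cloning)
#' @param vector a `vector_spec` (default the expression vector)
#' @param min_fragment_len minimal fragment length, nt (default 100)
#' @param max_cluster_span_nt see [cluster_mutations()]
#' @param max_overhang_shift maximal 5' shift of an overhang window, nt
#'   (default 6)
#' @param usage codon usage table for resolving point-mutation codons
#' @param allow_terminal allow mutating the start/stop codon (default FALSE)
#' @return object of class `fragment_plan`: list with `fragments`
#'   (data.frame: `start`, `end` 0-based half-open, `left_overhang`,
#'   `right_overhang` in sense-strand representation), `clusters`,
#'   `mutations` (resolved), `mutated_template`, `vector`
#' @export
plan_fragments <- function(seq, mutations = mutation_spec(integer(0),
                                                          character(0),
                                                          character(0)),
                           vector = PAGM22082_CRED,
                           min_fragment_len = 100L,
                           max_cluster_span_nt = 45L,
                           max_overhang_shift = 6L,
                           usage = codon_usage("e_coli"),
                           allow_terminal = FALSE) {
  if (is.character(vector)) vector <- get_vector(vector)
  s <- as_dna_string(seq)
  resolved <- resolve_mutations(s, mutations, usage, allow_terminal)
  plan_fragments_resolved(s, resolved, vector, min_fragment_len,
                          max_cluster_span_nt, max_overhang_shift)
}

#' @export
print.fragment_plan <- function(x, ...) {
  cat(sprintf("<fragment_plan> %d fragment(s) of a %d nt CDS, vector %s\n",
              nrow(x$fragments), nchar(x$template), x$vector$name))
  print(x$fragments)
  invisible(x)
}

# 0-based start offsets at which `pattern` certainly occurs in the possibly
# degenerate string `subject` (i.e. in every expansion): a literal match of
# the strict pattern, since any degenerate letter breaks certainty.
find_certain <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# 0-based start offsets at which `pattern` could occur in the possibly
# degenerate string `subject` (any expansion of subject matches there).
iupac_find_possible <- function(pattern, subject) {
  np <- nchar(pattern); ns <- nchar(subject)
  if (ns < np) return(integer(0))
  pb <- strsplit(pattern, "")[[1]]
  sb <- strsplit(subject, "")[[1]]
  hits <- integer(0)
  for (off in 0:(ns - np)) {
    ok <- TRUE
    for (j in seq_len(np)) {
      if (!pb[j] %in% IUPAC_CODES[[sb[off + j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# Assemble one structured primer and validate its grammar and site content.
make_primer <- function(fragment, direction, overhang_sense, insert,
                        binding_info, enzyme, padding, spacer) {
  overhang_segment <- if (direction == "forward") overhang_sense
                      else reverse_complement(overhang_sense)
  full <- paste0(padding, enzyme$recognition, spacer, overhang_segment,
                 insert, binding_info$sequence)
  # the binding region itself must be free of the design enzyme's site
  for (pat in c(enzyme$recognition, reverse_complement(enzyme$recognition))) {
    if (length(find_certain(pat, binding_info$sequence)) > 0L)
      stop("binding region of ", direction, " primer (fragment ", fragment,
           ") contains a ", enzyme$name, " site", call. = FALSE)
  }
  # the primer may carry the design enzyme's recognition sequence only
  # where intended; any other certain occurrence is a design error
  intended <- nchar(padding)
  variant_site_risk <- FALSE
  for (pat in c(enzyme$recognition, reverse_complement(enzyme$recognition))) {
    hits <- setdiff(find_certain(pat, full),
                    if (pat == enzyme$recognition) intended else integer(0))
    if (length(hits) > 0L)
      stop("primer for fragment ", fragment, " (", direction, ") contains ",
           "an extra ", enzyme$name, " site at offset ", hits[1],
           "; shift the junction overhang", call. = FALSE)
    # a site that only some expansions of a degenerate insert would form:
    # those library members are depleted by re-cutting (recorded, not fatal)
    possible <- setdiff(iupac_find_possible(pat, full),
                        if (pat == enzyme$recognition) intended
                        else integer(0))
    if (length(possible) > 0L) variant_site_risk <- TRUE
  }
  structure(list(fragment = fragment, direction = direction,
                 variant_site_risk = variant_site_risk,
                 padding = padding, recognition = enzyme$recognition,
                 spacer = spacer, overhang = overhang_segment,
                 overhang_sense = overhang_sense,
                 mutagenic_insert = insert,
                 binding = binding_info$sequence,
                 binding_region = binding_info$region,
                 binding_start = binding_info$start,
                 binding_end = binding_info$end,
                 binding_tm = binding_info$tm, low_tm = binding_info$low_tm,
                 full = full),
            class = "gg_primer")
}

#' @export
print.gg_primer <- function(x, ...) {
  cat(sprintf("<gg_primer> frag %d %s  %s|%s|%s|%s|%s|%s  Tm %.1f C%s\n",
              x$fragment, x$direction, x$padding, x$recognition, x$spacer,
              x$overhang, if (nzchar(x$mutagenic_insert)) x$mutagenic_insert
              else "-", x$binding, x$binding_tm,
              if (x$low_tm) " (low-Tm)" else ""))
  invisible(x)
}

#' Build the mutagenic primer set for a fragment plan
#'
#' For every fragment a forward and a reverse primer are assembled as
#' `padding + recognition + spacer + overhang + mutagenic_insert + binding`
#' (5' to 3', reverse primers in their own orientation). Saturation codons
#' sit in the mutagenic insert between the overhang and the binding region,
#' never inside the overhang; intervening wild-type codons within a cluster
#' are carried verbatim. Binding regions are grown to the target Tm and the
#' two primers of a pair are re-extended until their Tm difference is within
#' `pair_tm_tol`.
#'
#' @param plan a `fragment_plan`
#' @param target_tm binding-region target melting temperature, C (default 60)
#' @param pair_tm_tol maximal |Tm(fwd) - Tm(rev)| per pair, C (default 5)
#' @param padding 5' padding before the recognition site (default `"TT"`)
#' @param spacer_base base used to fill the enzyme spacer (default `"A"`)
#' @return object of class `design_result`: `plan`, `primers` (list of
#'   `gg_primer`, pairs in fragment order), `vector`, `protocol_text`
#' @export
build_primers <- function(plan, target_tm = 60, pair_tm_tol = 5,
                          padding = "TT", spacer_base = "A") {
  stopifnot(inherits(plan, "fragment_plan"))
  vec <- plan$vector
  enz <- vec$enzyme
  spacer <- strrep(spacer_base, enz$spacer_len)
  s <- plan$template
  mt <- plan$mutated_template
  L <- nchar(s)
  frag <- plan$fragments
  K <- nrow(frag)

  primers <- list()
  for (k in seq_len(K)) {
    # ---- forward primer of fragment k
    if (k == 1L) {
      oh <- vec$five_prime_overhang
      insert <- ""
      anchor <- vec$five_template_overlap
    } else {
      j <- plan$junctions[[k - 1L]]
      oh <- j$overhang
      cl <- j$cluster
      e <- 3L * cl[length(cl)]                       # 0-based end of cluster
      insert <- substr(mt, j$window_start + 5L, e)   # carries the mutations
      anchor <- e
    }
    fwd_bind <- extend_binding(s, anchor, "forward", target_tm)
    # ---- reverse primer of fragment k
    if (k == K) {
      oh_r <- vec$three_prime_overhang
      anchor_r <- L
    } else {
      # the overhang segment is itself template sequence; the binding
      # region continues 5' of the window, so both segments anneal
      oh_r <- plan$junctions[[k]]$overhang
      anchor_r <- plan$junctions[[k]]$window_start
    }
    rev_bind <- extend_binding(s, anchor_r, "reverse", target_tm)
    # balance the pair: extend the cooler primer toward the hotter one
    bal <- balance_pair(s, fwd_bind, rev_bind, anchor, anchor_r,
                        target_tm, pair_tm_tol)
    fwd_bind <- bal$fwd; rev_bind <- bal$rev
    if (fwd_bind$end > rev_bind$start)
      stop("fragment ", k, " too short: forward and reverse binding regions ",
           "overlap", call. = FALSE)
    primers[[length(primers) + 1L]] <-
      make_primer(k, "forward", oh, insert, fwd_bind, enz, padding, spacer)
    primers[[length(primers) + 1L]] <-
      make_primer(k, "reverse", oh_r, "", rev_bind, enz, padding, spacer)
  }
  out <- structure(list(plan = plan, primers = primers, vector = vec,
                        params = list(target_tm = target_tm,
                                      pair_tm_tol = pair_tm_tol,
                                      padding = padding,
                                      spacer_base = spacer_base),
                        protocol_text = NULL),
                   class = "design_result")
  out$protocol_text <- render_protocol(out)
  out
}

# Re-extend the cooler binding region of a pair until the Tm gap closes (or
# the 45 nt cap / template is exhausted).
balance_pair <- function(template, fwd, rev, anchor_f, anchor_r,
                         target_tm, tol) {
  max_len <- 45L
  repeat {
    gap <- fwd$tm - rev$tm
    if (abs(gap) <= tol) break
    if (gap < 0) {  # forward cooler
      len <- fwd$end - fwd$start
      if (len >= max_len || fwd$end >= nchar(template)) break
      fwd <- extend_binding(template, anchor_f, "forward",
                            target_tm = rev$tm - tol, max_len = max_len)
      if (fwd$tm - rev$tm == gap) break
    } else {
      len <- rev$end - rev$start
      if (len >= max_len || rev$start <= 0L) break
      rev <- extend_binding(template, anchor_r, "reverse",
                            target_tm = fwd$tm - tol, max_len = max_len)
      if (fwd$tm - rev$tm == gap) break
    }
  }
  list(fwd = fwd, rev = rev)
}

#' One-step or two-step workflow recommendation
#'
#' Direct assembly into the expression vector (one step, BsaI primers) is
#' recommended for designs with 3 or fewer PCR fragments; larger designs go
#' through per-fragment BbsI subcloning into pAGM9121 followed by BsaI
#' reassembly (two steps). The user may always override.
#'
#' @param n_fragments number of PCR fragments (>= 1)
#' @return `"one_step"` or `"two_step"`
#' @export
choose_workflow <- function(n_fragments) {
  stopifnot(n_fragments >= 1L)
  if (n_fragments <= 3L) "one_step" else "two_step"
}

#' Extract a tidy primer table from a design
#'
#' @param result a `design_result`
#' @return data.frame: fragment, direction, segment columns, full sequence
#'   (5' to 3'), binding length and Tm
#' @export
primer_table <- function(result) {
  stopifnot(inherits(result, "design_result"))
  do.call(rbind, lapply(result$primers, function(p) {
    data.frame(fragment = p$fragment, direction = p$direction,
               padding = p$padding, recognition = p$recognition,
               spacer = p$spacer, overhang = p$overhang,
               mutagenic_insert = p$mutagenic_insert, binding = p$binding,
               full_sequence = p$full, length = nchar(p$full),
               binding_tm = round(p$binding_tm, 2), low_tm = p$low_tm)
  }))
}

#' Write the primer table to CSV or JSON
#' @param result a `design_result`
#' @param path output path (`.csv` or `.json`)
#' @return `path`, invisibly
#' @export
write_primer_table <- function(result, path) {
  tab <- primer_table(result)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  else if (ext == "json")
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  else stop("unsupported primer table format: .", ext, call. = FALSE)
  invisible(path)
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> %d fragment(s), %d primers, vector %s (%s)\n",
              nrow(x$plan$fragments), length(x$primers), x$vector$name,
              x$vector$enzyme$name))
  for (p in x$primers) print(p)
  invisible(x)
}
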