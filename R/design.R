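# Top-level design workflow: domestication handling, fragmentation, primer
# construction and the human-readable protocol.

#' Design a complete Golden Gate mutagenesis primer set
#'
#' The main entry point. For point-mutagenesis designs, internal BsaI/BbsI
#' sites are detected and their silent removal is folded into the same
#' design pass: each silent fix becomes an additional junction, exactly like
#' a user-requested point mutation. For saturation designs the gene is
#' expected to be domesticated already; remaining internal sites trigger a
#' warning (and will make the in-silico assembly fail), since saturation
#' libraries should be built on a domesticated gene once and for all.
#'
#' @param seq wild-type CDS (`nt_sequence` with `is_cds = TRUE`, or string)
#' @param mutations mutation spec data.frame ([mutation_spec()] /
#'   [parse_mutations()]); may be empty for wild-type cloning
#' @param vector a `vector_spec` or its name (default `"pAGM22082_CRed"`)
#' @param usage codon usage table or organism name (default E. coli)
#' @param auto_domesticate fold silent fixes for internal sites into the
#'   design (default `TRUE` when any point mutation is requested or when no
#'   mutations are given, `FALSE` for pure saturation designs)
#' @param target_tm,pair_tm_tol,min_fragment_len,max_cluster_span_nt,max_overhang_shift,padding,spacer_base,allow_terminal
#'   tuning parameters, see [plan_fragments()] and [build_primers()]
#' @return a `design_result` (see [build_primers()]) with extra fields
#'   `fixes` (silent domestication fixes incorporated, possibly empty) and
#'   `workflow` (`"one_step"`/`"two_step"` recommendation)
#' @export
design_mutagenesis <- function(seq, mutations = mutation_spec(integer(0),
                                                              character(0),
                                                              character(0)),
                               vector = "pAGM22082_CRed",
                               usage = codon_usage("e_coli"),
                               auto_domesticate = NULL,
                               target_tm = 60, pair_tm_tol = 5,
                               min_fragment_len = 100L,
                               max_cluster_span_nt = 45L,
                               max_overhang_shift = 6L,
                               padding = "TT", spacer_base = "A",
                               allow_terminal = FALSE) {
  if (is.character(vector)) vector <- get_vector(vector)
  if (is.character(usage)) usage <- codon_usage(usage)
  s <- if (inherits(seq, "nt_sequence")) seq else nt_sequence(seq, is_cds = TRUE)

  pure_saturation <- nrow(mutations) > 0L && all(mutations$mode == "saturation")
  if (is.null(auto_domesticate)) auto_domesticate <- !pure_saturation

  fixes <- data.frame(codon_index = integer(0), old_codon = character(0),
                      new_codon = character(0), usage_freq = numeric(0))
  all_mut <- resolve_mutations(s, mutations, usage, allow_terminal)
  if (auto_domesticate) {
    dom <- domesticate(s, usage)
    fixes <- dom$fixes
    if (nrow(fixes) > 0L) {
      clash <- intersect(fixes$codon_index, all_mut$aa_position)
      if (length(clash))
        stop("internal site fix collides with requested mutation at codon ",
             paste(clash, collapse = ", "), call. = FALSE)
      fix_mut <- data.frame(aa_position = fixes$codon_index, mode = "point",
                            target = vapply(fixes$new_codon, function(cd)
                              GENETIC_CODE_TABLE[[cd]], character(1)),
                            wt_codon = fixes$old_codon,
                            new_codon = fixes$new_codon)
      if ("wt_aa" %in% names(all_mut)) fix_mut$wt_aa <- NA_character_
      all_mut <- rbind(all_mut[names(fix_mut)], fix_mut)
      all_mut <- all_mut[order(all_mut$aa_position), , drop = FALSE]
      rownames(all_mut) <- NULL
    }
  } else {
    hits <- scan_sites(s, list(BSAI, BBSI))
    if (nrow(hits) > 0L)
      warning("the CDS still contains ", nrow(hits), " internal BsaI/BbsI ",
              "site(s); domesticate it first (domesticate()) before building ",
              "a saturation library", call. = FALSE)
  }

  plan <- plan_fragments_resolved(s, all_mut, vector, min_fragment_len,
                                  max_cluster_span_nt, max_overhang_shift)
  result <- build_primers(plan, target_tm, pair_tm_tol, padding, spacer_base)
  result$fixes <- fixes
  result$workflow <- choose_workflow(nrow(plan$fragments))
  result$protocol_text <- render_protocol(result)
  result
}

# Would a junction at window [p, p+4) give primers free of accidental
# enzyme sites? Prefigures the build-time check on the junction-local
# primer content (default padding/spacer), so the planner can shift the
# window instead of failing later.
junction_site_free <- function(wt, mt, p, e, enzyme) {
  pad <- "TT"
  spacer <- strrep("A", enzyme$spacer_len)
  w <- substr(mt, p + 1L, p + 4L)
  fwd_ctx <- paste0(pad, enzyme$recognition, spacer, w,
                    substr(mt, p + 5L, e),
                    substr(wt, e + 1L, min(e + 45L, nchar(wt))))
  rev_ctx <- paste0(pad, enzyme$recognition, spacer, reverse_complement(w),
                    reverse_complement(substr(wt, max(1L, p - 44L), p)))
  for (ctx in list(fwd_ctx, rev_ctx)) {
    for (pat in c(enzyme$recognition,
                  reverse_complement(enzyme$recognition))) {
      hits <- setdiff(find_certain(pat, ctx),
                      if (pat == enzyme$recognition) nchar(pad)
                      else integer(0))
      if (length(hits) > 0L) return(FALSE)
    }
  }
  TRUE
}

# plan_fragments for an already-resolved mutation table (wt/new codons set).
plan_fragments_resolved <- function(seq, resolved, vector, min_fragment_len,
                                    max_cluster_span_nt, max_overhang_shift) {
  s <- as_dna_string(seq)
  mt <- apply_mutations(s, resolved)
  clusters <- cluster_mutations(resolved$aa_position, max_cluster_span_nt)
  used <- c(vector$five_prime_overhang, vector$three_prime_overhang)
  junctions <- list()
  for (cl in clusters) {
    b <- 3L * (cl[1] - 1L)
    e <- 3L * cl[length(cl)]
    chosen <- NULL
    for (shift in 0:max_overhang_shift) {
      p <- b - 4L - shift
      if (p < 0L) break
      w <- substr(s, p + 1L, p + 4L)
      if (overhang_ok(w, used) &&
          junction_site_free(s, mt, p, e, vector$enzyme)) {
        chosen <- list(window_start = p, overhang = w, shift = shift,
                       cluster = cl)
        break
      }
    }
    if (is.null(chosen))
      stop("no valid overhang window within ", max_overhang_shift,
           " nt 5' of codon ", cl[1], call. = FALSE)
    used <- c(used, chosen$overhang)
    junctions[[length(junctions) + 1L]] <- chosen
  }
  L <- nchar(s)
  bounds <- c(0L, vapply(junctions, `[[`, integer(1), "window_start"), L)
  lens <- diff(bounds)
  if (any(lens < min_fragment_len))
    stop("fragment too short: lengths ", paste(lens, collapse = ", "),
         " nt with min_fragment_len = ", min_fragment_len,
         "; consider merging clusters (larger max_cluster_span_nt)",
         call. = FALSE)
  frag <- data.frame(
    start = bounds[-length(bounds)],
    end = bounds[-1],
    left_overhang = c(vector$five_prime_overhang,
                      vapply(junctions, `[[`, character(1), "overhang")),
    right_overhang = c(vapply(junctions, `[[`, character(1), "overhang"),
                       vector$three_prime_overhang))
  structure(list(fragments = frag, junctions = junctions,
                 clusters = clusters, mutations = resolved,
                 template = s, mutated_template = mt, vector = vector,
                 min_fragment_len = as.integer(min_fragment_len),
                 max_cluster_span_nt = as.integer(max_cluster_span_nt),
                 max_overhang_shift = as.integer(max_overhang_shift)),
            class = "fragment_plan")
}

#' Render the deterministic plain-text bench protocol for a design
#'
#' Primer table, PCR recipe, one-pot restriction-ligation recipe and
#' transformation notes for the design's vector. Two renderings of the same
#' design are byte-identical.
#'
#' @param result a `design_result`
#' @return character scalar (the protocol text)
#' @export
render_protocol <- function(result) {
  stopifnot(inherits(result, "design_result"))
  vec <- result$vector
  enz <- vec$enzyme
  nfrag <- nrow(result$plan$fragments)
  wf <- choose_workflow(nfrag)
  l <- character(0)
  add <- function(...) l <<- c(l, paste0(...))
  add("GOLDEN GATE MUTAGENESIS PROTOCOL")
  add(strrep("=", 60))
  add("")
  add(sprintf("Design: %d fragment(s), %d primers, vector %s (enzyme %s).",
              nfrag, length(result$primers), vec$name, enz$name))
  add(sprintf("Recommended workflow: %s (%s).", wf,
              if (wf == "one_step")
                "3 or fewer PCR fragments: direct one-pot assembly"
              else
                "more than 3 fragments: subclone each fragment into pAGM9121, then reassemble"))
  add("")
  add("PRIMERS (5' -> 3'; padding|recognition|spacer|overhang|insert|binding)")
  add(strrep("-", 60))
  for (p in result$primers) {
    add(sprintf("fragment %d %-7s  %s", p$fragment, p$direction, p$full))
    add(sprintf("  segments: %s | %s | %s | %s | %s | %s   binding Tm %.1f C%s",
                p$padding, p$recognition, p$spacer, p$overhang,
                if (nzchar(p$mutagenic_insert)) p$mutagenic_insert else ".",
                p$binding, p$binding_tm, if (p$low_tm) "  [low-Tm]" else ""))
  }
  add("")
  add("PCR (per fragment, 50 ul)")
  add(strrep("-", 60))
  add("  100 ng template plasmid; 1x Phusion HF buffer; 3% (v/v) DMSO;")
  add("  200 uM dNTPs; 0.2 uM each primer; 0.5 U Phusion polymerase.")
  add("  Cycling: 98 C 60 s; 35x [95 C 15 s, 60 C 30 s, 72 C 90 s/kb];")
  add("  final extension 72 C 10 min. Verify fragment sizes on a 1-2.5%")
  add("  agarose gel and column-purify.")
  add("")
  add("ONE-POT RESTRICTION-LIGATION (15 ul)")
  add(strrep("-", 60))
  add(sprintf("  20 fmol acceptor vector %s, 20 fmol of each purified", vec$name))
  add("  fragment, 1x T4 ligase buffer, water to 13.5 ul; then add 0.5 ul")
  add(sprintf("  %s and 1 ul T4 DNA ligase (1-3 U).", enz$name))
  add("  Cycling: 40x [37 C 2 min, 20 C 5 min]; inactivation 80 C 20 min.")
  add("")
  add("TRANSFORMATION")
  add(strrep("-", 60))
  if (vec$name == "pAGM9121") {
    add("  Transform the whole 15 ul into an E. coli cloning strain (e.g.")
    add("  DH10B). Plate on LB + spectinomycin + X-Gal + IPTG: recombinant")
    add("  clones are white, re-ligated empty vector is blue (LacZ).")
    add("  For library fragments, inoculate the transformation directly")
    add("  into liquid culture to preserve degeneracy.")
  } else {
    add("  Transform into an E. coli BL21(DE3) pLysS expression strain.")
    add("  Plate on LB + kanamycin + chloramphenicol: recombinant clones")
    add("  are white, uncut vector retains the orange CRed (canthaxanthin)")
    add("  marker. Expression from the T7 promoter (IPTG induction).")
  }
  add("")
  paste(l, collapse = "\n")
}

#' Write a machine-readable design report (JSON)
#'
#' Contains everything needed to re-simulate or QQC the design: vector,
#' parameters, fragment plan, mutation table and the complete primer set.
#'
#' @param result a `design_result`
#' @param path output `.json` path
#' @return `path`, invisibly
#' @export
write_design_json <- function(result, path) {
  stopifnot(inherits(result, "design_result"))
  plan <- result$plan
  rpt <- list(
    vector = result$vector$name,
    enzyme = result$vector$enzyme$name,
    workflow = if (!is.null(result$workflow)) result$workflow
               else choose_workflow(nrow(plan$fragments)),
    params = c(list(min_fragment_len = plan$min_fragment_len,
                    max_cluster_span_nt = plan$max_cluster_span_nt,
                    max_overhang_shift = plan$max_overhang_shift),
               result$params),
    template = plan$template,
    mutated_template = plan$mutated_template,
    mutations = plan$mutations,
    fixes = result$fixes,
    fragments = plan$fragments,
    primers = primer_table(result))
  jsonlite::write_json(rpt, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a design report JSON back into a `design_result`-like list
#'
#' Rebuilds the design by re-running the planner on the stored template and
#' mutation table, then checks that the stored primers match. Used by the
#' command-line `simulate` and `qqc` subcommands.
#'
#' @param path a design report written by [write_design_json()]
#' @return a `design_result`
#' @export
read_design_json <- function(path) {
  rpt <- jsonlite::read_json(path, simplifyVector = TRUE)
  mut <- as.data.frame(rpt$mutations)
  if (nrow(mut) == 0L)
    mut <- data.frame(aa_position = integer(0), mode = character(0),
                      target = character(0), wt_codon = character(0),
                      new_codon = character(0))
  prm <- rpt$params
  plan <- plan_fragments_resolved(rpt$template, mut, get_vector(rpt$vector),
                                  min_fragment_len = prm$min_fragment_len,
                                  max_cluster_span_nt = prm$max_cluster_span_nt,
                                  max_overhang_shift = prm$max_overhang_shift)
  result <- build_primers(plan, target_tm = prm$target_tm,
                          pair_tm_tol = prm$pair_tm_tol,
                          padding = prm$padding, spacer_base = prm$spacer_base)
  stored <- as.data.frame(rpt$primers)
  rebuilt <- primer_table(result)
  if (!identical(stored$full_sequence, rebuilt$full_sequence))
    warning("stored primer sequences differ from the rebuilt design; ",
            "using the rebuilt primers", call. = FALSE)
  if (!is.null(rpt$fixes)) result$fixes <- as.data.frame(rpt$fixes)
  result$workflow <- rpt$workflow
  result
}
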