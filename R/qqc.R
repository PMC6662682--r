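# Quick Quality Control: locate the randomized codons of a design in a
# pooled-library Sanger read and report per-position A/C/G/T proportions
# from the chromatogram channels, plus a divergence score against the
# intended degeneracy.

# Maximal strict (non-degenerate) runs of a reference, as 0-based
# half-open intervals.
strict_runs <- function(reference) {
  b <- strsplit(as_dna_string(reference), "")[[1]]
  strict <- b %in% STRICT_BASES
  r <- rle(strict)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Locate the randomized codons of a design in a Sanger read
#'
#' Anchors the read to the reference by exact matching of the longest
#' non-degenerate reference segment (>= `min_anchor` nt), extends the
#' ungapped alignment both ways, and requires at least 80% identity over at
#' least 60 aligned nt (degenerate reference positions excluded). Reverse
#' reads are matched against the reverse complement and mapped back through
#' coordinate reflection.
#'
#' @param trace a `chromatogram_trace`
#' @param reference the designed insert sequence: the mutated template with
#'   degenerate codes at saturation codons (a string, or a `design_result`
#'   whose mutated template is used)
#' @param design optional `design_result`; its saturation positions are the
#'   codons located (otherwise the degenerate codons of `reference`)
#' @param read_direction `"forward"` or `"reverse"`
#' @param min_anchor minimal exact anchor length (default 20)
#' @return named list mapping codon index to the three 1-based trace call
#'   positions covering the codon (5'->3' on the reference)
#' @export
locate_randomized_positions <- function(trace, reference, design = NULL,
                                        read_direction = c("forward",
                                                           "reverse"),
                                        min_anchor = 20L) {
  read_direction <- match.arg(read_direction)
  if (inherits(reference, "design_result")) {
    design <- reference
    reference <- design$plan$mutated_template
  }
  ref <- as_dna_string(reference)
  read <- trace$basecalls
  work <- if (read_direction == "reverse") reverse_complement(read) else read
  n_read <- nchar(read)

  runs <- strict_runs(ref)
  runs <- runs[runs$end - runs$start >= min_anchor, , drop = FALSE]
  runs <- runs[order(-(runs$end - runs$start)), , drop = FALSE]
  offset <- NULL
  for (i in seq_len(nrow(runs))) {
    seg <- substr(ref, runs$start[i] + 1L, runs$end[i])
    hit <- regexpr(seg, work, fixed = TRUE)
    if (hit > 0L) {
      offset <- (hit - 1L) - runs$start[i]   # read_pos0 = ref_pos0 + offset
      break
    }
  }
  if (is.null(offset))
    stop("read does not match reference: no exact anchor of >= ",
         min_anchor, " nt", call. = FALSE)

  # ungapped identity over the aligned overlap, degenerate positions masked
  ref_b <- strsplit(ref, "")[[1]]
  work_b <- strsplit(work, "")[[1]]
  ref_idx <- seq_along(ref_b)
  read_idx <- ref_idx + offset
  keep <- read_idx >= 1L & read_idx <= n_read
  strict <- ref_b %in% STRICT_BASES
  cmp <- keep & strict
  n_aligned <- sum(cmp)
  if (n_aligned < 60L)
    stop("read does not match reference: aligned overlap ", n_aligned,
         " nt < 60 nt", call. = FALSE)
  identity <- mean(ref_b[cmp] == work_b[read_idx[cmp]])
  if (identity < 0.8)
    stop("read does not match reference: identity ",
         sprintf("%.1f%%", 100 * identity), " < 80%", call. = FALSE)

  sat_codons <- if (!is.null(design)) {
    mu <- design$plan$mutations
    sort(mu$aa_position[mu$mode == "saturation"])
  } else {
    deg <- which(!strict)
    sort(unique((deg - 1L) %/% 3L + 1L))
  }
  out <- list()
  for (ci in sat_codons) {
    ref_pos <- 3L * (ci - 1L) + 1:3          # 1-based reference positions
    work_pos <- ref_pos + offset             # positions in `work`
    if (any(work_pos < 1L | work_pos > n_read))
      stop("randomized codon ", ci, " not covered by the read", call. = FALSE)
    trace_pos <- if (read_direction == "reverse")
      n_read - work_pos + 1L else work_pos   # reflect back to trace calls
    out[[as.character(ci)]] <- as.integer(trace_pos)
  }
  out
}

#' Extract base distributions at trace positions
#'
#' At each call position the proportion of base b is its channel intensity
#' at the call's peak divided by the sum of the four channels. For reverse
#' reads the base labels are complemented so proportions are reported in
#' reference (sense) orientation.
#'
#' @param trace a `chromatogram_trace`
#' @param positions named list codon index -> three 1-based call positions
#'   (as from [locate_randomized_positions()]), or an integer vector of
#'   call positions
#' @param read_direction `"forward"` or `"reverse"`
#' @return data.frame: `codon_index`, `offset` (1-3 within the codon, NA for
#'   bare positions), `position` (trace call), `A`, `C`, `G`, `T`
#'   (proportions summing to 1)
#' @export
extract_distributions <- function(trace, positions,
                                  read_direction = c("forward", "reverse")) {
  read_direction <- match.arg(read_direction)
  if (!is.list(positions)) positions <- list(as.integer(positions))
  nms <- names(positions)
  rows <- list()
  for (idx in seq_along(positions)) {
    nm <- if (is.null(nms) || is.na(nms[idx])) NA_character_ else nms[idx]
    pv <- positions[[idx]]
    for (j in seq_along(pv)) {
      pos <- pv[j]
      if (pos < 1L || pos > nrow(trace$channels))
        stop("position ", pos, " outside trace", call. = FALSE)
      inten <- trace$channels[pos, STRICT_BASES]
      tot <- sum(inten)
      if (tot <= 0)
        stop("dead peak: all four channels are zero at call position ", pos,
             call. = FALSE)
      prop <- inten / tot
      if (read_direction == "reverse")
        prop <- stats::setNames(prop[c("T", "G", "C", "A")], STRICT_BASES)
      rows[[length(rows) + 1L]] <- data.frame(
        codon_index = if (is.na(nm)) NA_integer_ else as.integer(nm),
        offset = if (length(pv) == 3L) j else NA_integer_,
        position = pos,
        A = prop[["A"]], C = prop[["C"]], G = prop[["G"]], T = prop[["T"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total-variation divergence of an observed base distribution from the
#' intended degeneracy
#'
#' The expected distribution at one codon offset is uniform over the bases
#' allowed by the degenerate code at that offset (disallowed bases expected
#' at 0). The score is the total-variation distance, in `[0, 1]`; 0 means a
#' perfect match. Against a fully degenerate N the maximum is 0.75.
#'
#' @param proportions numeric length 4, named or ordered A, C, G, T
#' @param code the IUPAC code expected at this position (e.g. `"N"`, `"D"`)
#' @return the TV distance (numeric scalar)
#' @export
compare_to_degeneracy <- function(proportions, code) {
  p <- as.numeric(proportions)
  if (!is.null(names(proportions))) p <- as.numeric(proportions[STRICT_BASES])
  stopifnot(length(p) == 4L, all(p >= -1e-9), abs(sum(p) - 1) < 1e-6)
  allowed <- IUPAC_CODES[[toupper(code)]]
  if (is.null(allowed)) stop("unknown IUPAC code '", code, "'", call. = FALSE)
  q <- stats::setNames(rep(0, 4), STRICT_BASES)
  q[allowed] <- 1 / length(allowed)
  0.5 * sum(abs(p - q))
}

#' Run the full QQC analysis of one chromatogram against a design
#'
#' @param trace a `chromatogram_trace` (or a path to an `.ab1` file)
#' @param design a `design_result` with saturation mutations
#' @param read_direction `"forward"` or `"reverse"`
#' @return data.frame: `codon_index`, `offset`, `position`, `A`, `C`, `G`,
#'   `T`, `expected_code`, `tv`
#' @export
qqc_analysis <- function(trace, design,
                         read_direction = c("forward", "reverse")) {
  read_direction <- match.arg(read_direction)
  if (is.character(trace)) trace <- read_abif(trace)
  pos <- locate_randomized_positions(trace, design,
                                     read_direction = read_direction)
  dist <- extract_distributions(trace, pos, read_direction)
  mu <- design$plan$mutations
  codon_of <- stats::setNames(mu$new_codon, as.character(mu$aa_position))
  dist$expected_code <- vapply(seq_len(nrow(dist)), function(i) {
    substr(codon_of[[as.character(dist$codon_index[i])]], dist$offset[i],
           dist$offset[i])
  }, character(1))
  dist$tv <- vapply(seq_len(nrow(dist)), function(i) {
    compare_to_degeneracy(c(A = dist$A[i], C = dist$C[i], G = dist$G[i],
                            T = dist$T[i]), dist$expected_code[i])
  }, numeric(1))
  dist
}

# pie-chart colors: adenine red, cytosine orange, guanine green, thymine blue
QQC_COLORS <- c(A = "#e41a1c", C = "#ff7f00", G = "#4daf4a", T = "#377eb8")

#' Render the QQC report: per-position pie charts and a CSV table
#'
#' One pie chart per randomized position (3 per codon), colored red/orange/
#' green/blue for A/C/G/T, plus a CSV of proportions and TV scores.
#' Rendering is deterministic for fixed inputs.
#'
#' @param distributions output of [qqc_analysis()] (or
#'   [extract_distributions()] plus scores)
#' @param file_prefix output prefix; writes `<prefix>.png` and
#'   `<prefix>.csv`
#' @param width,height PNG size in pixels
#' @return character vector of the two file paths, invisibly
#' @export
render_qqc_report <- function(distributions, file_prefix,
                              width = 900, height = 700) {
  stopifnot(nrow(distributions) >= 1L)
  csv_path <- paste0(file_prefix, ".csv")
  png_path <- paste0(file_prefix, ".png")
  utils::write.csv(distributions, csv_path, row.names = FALSE, quote = FALSE)
  n <- nrow(distributions)
  ncol_panel <- 3L
  nrow_panel <- ceiling(n / ncol_panel)
  grDevices::png(png_path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(nrow_panel, ncol_panel), mar = c(1, 1, 3, 1))
  for (i in seq_len(n)) {
    p <- c(A = distributions$A[i], C = distributions$C[i],
           G = distributions$G[i], T = distributions$T[i])
    keep <- p > 1e-3
    title <- sprintf("codon %s pos %s%s",
                     distributions$codon_index[i], distributions$offset[i],
                     if ("tv" %in% names(distributions))
                       sprintf(" (TV %.2f)", distributions$tv[i]) else "")
    graphics::pie(p[keep], labels = sprintf("%s %.0f%%", names(p)[keep],
                                            100 * p[keep]),
                  col = QQC_COLORS[names(p)[keep]], clockwise = TRUE,
                  main = title)
  }
  invisible(c(png = png_path, csv = csv_path))
}
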