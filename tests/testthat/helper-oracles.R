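# Independent oracles used across the suite. Each one is deliberately a
# different implementation path from the package code it checks.

# random strict DNA string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive O(n*m) both-strand substring search for recognition sites
naive_scan <- function(seq, enzymes = list(BSAI, BBSI)) {
  s <- toupper(as.character(seq))
  hits <- list()
  for (enz in enzymes) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") enz$recognition
             else reverse_complement(enz$recognition)
      m <- nchar(pat)
      if (nchar(s) < m) next
      for (i in 0:(nchar(s) - m)) {
        if (substr(s, i + 1, i + m) == pat)
          hits[[length(hits) + 1]] <- c(enz$name, strand, i)
      }
    }
  }
  if (!length(hits)) return(character(0))
  keys <- vapply(hits, function(h) paste(h, collapse = ":"), character(1))
  sort(keys)
}

scan_keys <- function(hits) {
  if (nrow(hits) == 0) return(character(0))
  sort(paste(hits$enzyme, hits$strand, hits$start, sep = ":"))
}

# brute-force clustering: all mutations whose codon windows chain within
# the span cap, computed by exhaustive left-to-right grouping
naive_clusters <- function(positions, cap = 45L) {
  if (!length(positions)) return(list())
  out <- list()
  cur <- positions[1]
  for (p in positions[-1]) {
    if ((p - cur[1] + 1L) * 3L <= cap) cur <- c(cur, p)
    else { out[[length(out) + 1L]] <- cur; cur <- p }
  }
  out[[length(out) + 1L]] <- cur
  out
}

# batch nearest-neighbor Tm through an independent implementation
# (Biopython's Tm_NN with the same unified parameter set and conditions)
biopython_tm <- function(seqs) {
  inp <- tempfile(fileext = ".txt")
  out <- tempfile(fileext = ".txt")
  writeLines(seqs, inp)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from Bio.SeqUtils import MeltingTemp as mt",
    "def rc(s):",
    "    return s[::-1].translate(str.maketrans('ACGT', 'TGCA'))",
    sprintf("seqs = open(%s).read().split()", deparse(inp)),
    sprintf("with open(%s, 'w') as fh:", deparse(out)),
    "    for s in seqs:",
    "        fh.write('%.8f\\n' % mt.Tm_NN(s, nn_table=mt.DNA_NN3, Na=50,",
    "                 dnac1=250, dnac2=250, saltcorr=5,",
    "                 selfcomp=(s == rc(s))))"), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L)) return(NULL)
  as.numeric(readLines(out))
}

# a worked mCherry-like fixture: 711 nt synthetic CDS with one internal
# BbsI site planted mid-gene (same positional geometry as the real case:
# point mutation at codon 69 plus one site to domesticate)
mcherry_like <- function(seed = 3) {
  plant_site(synth_cds(237, seed = seed), BBSI, 450, "+")
}

# a worked YfeX-like fixture: 897 nt synthetic CDS (299 codons + stop
# handling: 299 total here) for the 5-site NDT geometry
yfex_like <- function(seed = 5) {
  synth_cds(299, seed = seed)
}
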