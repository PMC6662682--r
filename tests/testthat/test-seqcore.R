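test_that("reverse complement handles strict and degenerate codes", {
  expect_identical(reverse_complement("AATG"), "CATT")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("NDT"), "AHN")
  # degenerate complement is consistent with set expansion
  lhs <- sort(unname(vapply(expand_degenerate_codon("NDT"),
                            reverse_complement, character(1))))
  rhs <- sort(expand_degenerate_codon("AHN"))
  expect_identical(lhs, rhs)
  expect_error(reverse_complement("AXT"), "IUPAC")
})

test_that("reverse complement is an involution on random IUPAC strings", {
  set.seed(101)
  codes <- names(gatemut:::IUPAC_COMPLEMENT)
  for (i in 1:50) {
    s <- paste(sample(codes, sample(0:30, 1), replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("degenerate codon expansion matches the cardinality product", {
  expect_length(expand_degenerate_codon("NDT"), 12L)
  expect_length(expand_degenerate_codon("NNK"), 32L)
  expect_identical(expand_degenerate_codon("ATG"), "ATG")
  expect_error(expand_degenerate_codon("NXT"), "IUPAC")
  set.seed(7)
  codes <- names(gatemut:::IUPAC_CODES)
  for (i in 1:100) {
    cod <- paste(sample(codes, 3, replace = TRUE), collapse = "")
    expected <- prod(vapply(strsplit(cod, "")[[1]],
                            function(k) length(gatemut:::IUPAC_CODES[[k]]),
                            numeric(1)))
    got <- expand_degenerate_codon(cod)
    expect_length(got, expected)
    expect_false(anyDuplicated(got) > 0)
  }
})

test_that("overhang enumeration excludes exactly the palindromic 4-mers", {
  oh <- enumerate_valid_overhangs()
  expect_length(oh, 240L)
  expect_false("GATC" %in% oh)
  # brute-force palindrome census over all 256 4-mers
  g <- expand.grid(b1 = c("A","C","G","T"), b2 = c("A","C","G","T"),
                   b3 = c("A","C","G","T"), b4 = c("A","C","G","T"))
  all4 <- paste0(g$b1, g$b2, g$b3, g$b4)
  pal <- all4[vapply(all4, function(s)
    identical(s, reverse_complement(s)), logical(1))]
  expect_length(pal, 16L)
  expect_setequal(oh, setdiff(all4, pal))
})

test_that("translation follows the standard genetic code", {
  expect_identical(translate_dna("ATGGCTTAA"), "MA*")
  expect_identical(translate_dna("CTG"), "L")
  expect_error(translate_dna("ATGA"), "divisible")
  # spot-check against the Biostrings genetic code
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(3 * sample(1:30, 1))
    expect_identical(
      translate_dna(s),
      as.character(Biostrings::translate(Biostrings::DNAString(s),
                                         no.init.codon = TRUE)))
  }
})

test_that("CDS validation enforces frame, start, stop and internal stops", {
  expect_silent(nt_sequence("ATGGCTTAA", is_cds = TRUE))
  expect_error(nt_sequence("ATGGCTTA", is_cds = TRUE), "divisible")
  expect_error(nt_sequence("TTGGCTTAA", is_cds = TRUE), "ATG")
  expect_error(nt_sequence("ATGGCTGCT", is_cds = TRUE), "stop")
  expect_error(nt_sequence("ATGTAAGCTTAA", is_cds = TRUE), "internal stop")
})

test_that("FASTA round trip and multi-record handling", {
  cds <- synth_cds(100, seed = 2)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(cds, fa)
  back <- read_cds_fasta(fa)
  expect_identical(as.character(back), as.character(cds))
  # multi-record requires an id
  write_fasta(c(one = "ATGAAATAA", two = "ATGCCCTAA"), fa)
  expect_error(read_cds_fasta(fa), "multi-record")
  expect_identical(as.character(read_cds_fasta(fa, id = "two")), "ATGCCCTAA")
})

test_that("codon usage tables are per-amino-acid normalised", {
  for (org in c("e_coli", "s_cerevisiae", "a_thaliana")) {
    u <- codon_usage(org)
    sums <- tapply(u$fraction, u$aa, sum)
    expect_true(all(abs(sums - 1) < 1e-9), info = org)
  }
  u <- codon_usage("e_coli")
  expect_identical(preferred_codon(u, "M"), "ATG")
  expect_identical(preferred_codon(u, "K"), "AAA")
  expect_error(usage_fraction(u, "XYZ"), "unknown codon")
})
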