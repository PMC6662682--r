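test_that("simulate_pcr builds the product and rejects bad orientations", {
  cds <- synth_cds(250, seed = 10)
  d <- design_mutagenesis(cds, mutation_spec(120, "saturation", "NDT"))
  fwd <- d$primers[[3]]; rev <- d$primers[[4]]
  prod <- simulate_pcr(cds, fwd, rev)
  expect_match(prod, "NDT")
  expect_identical(substr(prod, 1, nchar(fwd$full)), fwd$full)
  expect_identical(substr(prod, nchar(prod) - nchar(rev$full) + 1,
                          nchar(prod)), reverse_complement(rev$full))
  expect_error(simulate_pcr(cds, rev, fwd), "does not anneal")
  # a foreign template does not amplify
  other <- synth_cds(250, seed = 11)
  expect_error(simulate_pcr(other, fwd, rev), "does not anneal")
})

test_that("digestion cut arithmetic matches a hand-worked product", {
  # TT GAAGAC AA CTCA AAACCC CGAG TT GTCTTC AA: BbsI(2/6) cuts leave the
  # CTCA / CGAG overhangs and the 6 nt core
  prod <- "TTGAAGACAACTCAAAACCCCGAGTTGTCTTCAA"
  fr <- digest(prod, BBSI)
  expect_identical(fr$left_overhang, "CTCA")
  expect_identical(fr$right_overhang, "CGAG")
  expect_identical(fr$core, "AAACCC")
})

test_that("digest recovers the designed overhangs from PCR products", {
  cds <- synth_cds(260, seed = 12)
  d <- design_mutagenesis(cds, mutation_spec(130, "saturation", "NDT"),
                          vector = "pAGM9121")
  for (k in 1:2) {
    prod <- simulate_pcr(cds, d$primers[[2 * k - 1]], d$primers[[2 * k]])
    fr <- digest(prod, BBSI)
    expect_identical(fr$left_overhang, d$plan$fragments$left_overhang[k])
    expect_identical(fr$right_overhang, d$plan$fragments$right_overhang[k])
  }
})

test_that("digest rejects internal and outward-facing sites", {
  prod <- "TTGAAGACAACTCAAAACCCCGAGTTGTCTTCAA"
  internal <- sub("AAACCC", "AAGAAGACCC", prod)  # extra BbsI site inside
  expect_error(digest(internal, BBSI), "internal site")
  outward <- "TTGTCTTCAACTCAAAACCCCGAGTTGAAGACAA"  # sites face away
  expect_error(digest(outward, BBSI), "orientation")
})

test_that("ligation demands a unique overhang chain", {
  mk <- function(l, core, r) structure(
    list(core = core, left_overhang = l, right_overhang = r),
    class = "digested_fragment")
  v <- PAGM9121  # CTCA ... CGAG
  ok <- ligate(list(mk("CTCA", "AAA", "GGAT"), mk("GGAT", "CCC", "CGAG")), v)
  expect_identical(ok$assembled_insert, "CTCAAAAGGATCCCCGAG")
  expect_identical(ok$assembled_cds, "AAAGGATCCC")
  expect_error(ligate(list(), v), "unassemblable")
  expect_error(ligate(list(mk("CTCA", "AAA", "GGAT"),
                           mk("TTAC", "CCC", "CGAG")), v), "unassemblable")
  expect_error(ligate(list(mk("CTCA", "AAA", "GGAT"),
                           mk("CTCA", "CCC", "CGAG")), v), "ambiguous")
})

test_that("wild-type designs round-trip byte-for-byte", {
  for (vec in list(PAGM9121, PAGM22082_CRED)) {
    cds <- synth_cds(220, seed = 33)
    d <- design_mutagenesis(cds, vector = vec)
    o <- verify_design(cds, NULL, d)
    expect_true(o$is_seamless)
    expect_identical(o$assembled_cds, as.character(cds))
    expect_length(o$mutated_codon_indices, 0L)
  }
})

test_that("point designs change exactly the requested codon", {
  cds <- mcherry_like()
  d <- design_mutagenesis(cds, mutation_spec(69, "point", "V"),
                          vector = "pAGM9121")
  expect_identical(nrow(d$plan$fragments), 3L)
  o <- verify_design(cds, NULL, d)
  expect_true(o$is_seamless)
  # the requested codon plus the silent domestication fix
  expect_identical(o$mutated_codon_indices,
                   sort(c(69L, d$fixes$codon_index)))
  expect_identical(substr(translate_dna(o$assembled_cds), 69, 69), "V")
  # everything else translates identically
  aa_wt <- translate_dna(cds)
  aa_new <- translate_dna(o$assembled_cds)
  expect_identical(substr(aa_wt, 70, nchar(aa_wt)),
                   substr(aa_new, 70, nchar(aa_new)))
})

test_that("saturation designs assemble seamlessly with confined changes", {
  set.seed(55)
  for (i in 1:20) {
    cds <- synth_cds(sample(200:500, 1), seed = 2000 + i)
    n_max <- max(1, min(5, (nchar(as.character(cds)) %/% 3 - 80) %/% 40 + 1))
    mut <- synth_mutations(cds, sample(1:n_max, 1), seed = i)
    d <- design_mutagenesis(cds, mut)
    o <- verify_design(cds, mut, d)
    expect_true(o$is_seamless, info = paste("fixture", i))
    expect_identical(o$mutated_codon_indices, mut$aa_position)
    # liberation: no assembly-enzyme site in the insert outside the
    # randomized codons (literal match on the symbolic sequence)
    rec <- d$vector$enzyme$recognition
    expect_false(grepl(rec, o$assembled_cds, fixed = TRUE))
    expect_false(grepl(reverse_complement(rec), o$assembled_cds,
                       fixed = TRUE))
  }
})
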