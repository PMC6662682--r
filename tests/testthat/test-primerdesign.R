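test_that("mutation clustering follows the span cap", {
  # 5-site geometry: {137,143,147} spans 33 nt, {232,234} spans 9 nt
  cl <- cluster_mutations(c(137L, 143L, 147L, 232L, 234L), 45L)
  expect_length(cl, 2L)
  expect_identical(cl[[1]], c(137L, 143L, 147L))
  expect_identical(cl[[2]], c(232L, 234L))
  expect_length(cluster_mutations(150L), 1L)
  expect_length(cluster_mutations(integer(0)), 0L)
  # agrees with the brute-force oracle on random position sets
  set.seed(3)
  for (i in 1:50) {
    pos <- sort(sample(2:400, sample(1:8, 1)))
    expect_identical(cluster_mutations(pos, 45L), naive_clusters(pos, 45L))
  }
})

test_that("fragment count is cluster count + 1", {
  cds <- synth_cds(300, seed = 4)
  # wild-type cloning: one fragment, two primers
  p0 <- plan_fragments(cds, vector = PAGM9121)
  expect_identical(nrow(p0$fragments), 1L)
  d0 <- build_primers(p0)
  expect_length(d0$primers, 2L)
  # one saturation site mid-gene: two fragments
  p1 <- plan_fragments(cds, mutation_spec(150, "saturation", "NDT"))
  expect_identical(nrow(p1$fragments), 2L)
  # five sites in two clusters: three fragments
  p5 <- plan_fragments(cds, mutation_spec(c(137, 143, 147, 232, 234),
                                          "saturation", "NDT"))
  expect_identical(nrow(p5$fragments), 3L)
  expect_length(build_primers(p5)$primers, 6L)
})

test_that("fragment plans tile the CDS with valid overhang sets", {
  set.seed(41)
  for (i in 1:10) {
    cds <- synth_cds(sample(250:400, 1), seed = 500 + i)
    mut <- synth_mutations(cds, sample(1:3, 1), seed = i)
    plan <- plan_fragments(cds, mut)
    fr <- plan$fragments
    # tiling: contiguous, in order, full coverage
    expect_identical(fr$start[1], 0L)
    expect_identical(fr$end[nrow(fr)], nchar(as.character(cds)))
    if (nrow(fr) > 1)
      expect_identical(fr$start[-1], fr$end[-nrow(fr)])
    expect_true(all(fr$end - fr$start >= 100))
    # overhang set validity: distinct, non-palindromic, non-complementary
    oh <- unique(c(fr$left_overhang, fr$right_overhang))
    expect_false(any(vapply(oh, is_palindromic_overhang, logical(1))))
    expect_identical(anyDuplicated(oh), 0L)
    expect_false(any(vapply(oh, reverse_complement, character(1)) %in% oh))
    # vector overhangs at the outer ends
    expect_identical(fr$left_overhang[1], plan$vector$five_prime_overhang)
    expect_identical(fr$right_overhang[nrow(fr)],
                     plan$vector$three_prime_overhang)
  }
})

test_that("primers follow the structural grammar with the BbsI prefix", {
  cds <- synth_cds(300, seed = 8)
  d <- design_mutagenesis(cds, mutation_spec(60, "saturation", "NDT"),
                          vector = "pAGM9121")
  for (p in d$primers) {
    expect_identical(p$full, paste0(p$padding, p$recognition, p$spacer,
                                    p$overhang, p$mutagenic_insert,
                                    p$binding))
  }
  fwd1 <- d$primers[[1]]
  expect_identical(substr(fwd1$full, 1, 14), "TTGAAGACAACTCA")
  # the saturation codon rides on the forward primer of fragment 2,
  # between the overhang and the binding region
  fwd2 <- d$primers[[3]]
  expect_match(fwd2$mutagenic_insert, "NDT$")
  expect_false(grepl("[^ACGT]", fwd2$overhang))
  expect_false(grepl("[^ACGT]", fwd2$binding))
})

test_that("point mutations are encoded in the primers, not the binding", {
  cds <- synth_cds(250, seed = 15)
  wt_aa <- substr(translate_dna(cds), 80, 80)
  target <- if (wt_aa == "V") "L" else "V"
  d <- design_mutagenesis(cds, mutation_spec(80, "point", target))
  mt <- d$plan$mutated_template
  expect_identical(substr(translate_dna(mt), 80, 80), target)
  # every binding region matches the wild-type template exactly
  s <- as.character(cds)
  for (p in d$primers) {
    expect_identical(substr(s, p$binding_start + 1, p$binding_end),
                     p$binding_region)
  }
})

test_that("primer pairs are Tm-balanced at the 60 C target", {
  set.seed(19)
  for (i in 1:15) {
    cds <- synth_cds(sample(220:350, 1), seed = 700 + i)
    mut <- synth_mutations(cds, sample(1:2, 1), seed = i)
    d <- design_mutagenesis(cds, mut)
    tms <- vapply(d$primers, `[[`, numeric(1), "binding_tm")
    flagged <- vapply(d$primers, `[[`, logical(1), "low_tm")
    expect_true(all(tms >= 57 | flagged))
    pair_gap <- abs(tms[c(TRUE, FALSE)] - tms[c(FALSE, TRUE)])
    expect_true(all(pair_gap <= 5 | flagged[c(TRUE, FALSE)] |
                      flagged[c(FALSE, TRUE)]))
  }
})

test_that("workflow choice follows the three-fragment rule", {
  expect_identical(choose_workflow(1), "one_step")
  expect_identical(choose_workflow(2), "one_step")
  expect_identical(choose_workflow(3), "one_step")
  expect_identical(choose_workflow(4), "two_step")
  expect_identical(choose_workflow(5), "two_step")
  expect_error(choose_workflow(0))
})

test_that("the rendered protocol is deterministic and complete", {
  cds <- synth_cds(250, seed = 6)
  d <- design_mutagenesis(cds, mutation_spec(120, "saturation", "NNK"),
                          vector = "pAGM9121")
  txt <- render_protocol(d)
  expect_identical(txt, render_protocol(d))
  for (p in d$primers) expect_true(grepl(p$full, txt, fixed = TRUE))
  expect_match(txt, "BbsI")
  expect_match(txt, "pAGM9121")
  d2 <- design_mutagenesis(cds, mutation_spec(120, "saturation", "NNK"))
  expect_match(render_protocol(d2), "BsaI")
  expect_match(render_protocol(d2), "pAGM22082_CRed")
  expect_match(render_protocol(d2), "one_step")
})

test_that("mutation token parsing accepts both grammars", {
  m <- parse_mutations(c("D137N", "143:NDT"))
  expect_identical(m$aa_position, c(137L, 143L))
  expect_identical(m$mode, c("point", "saturation"))
  expect_identical(m$target, c("N", "NDT"))
  expect_error(parse_mutations("137NDT"), "cannot parse")
  # wild-type residue mismatch is caught at design time
  cds <- synth_cds(200, seed = 44)
  wt <- substr(translate_dna(cds), 90, 90)
  wrong <- setdiff(c("A", "G", "L"), wt)[1]
  tok <- paste0(wrong, 90, if (wt == "V") "L" else "V")
  expect_error(design_mutagenesis(cds, parse_mutations(tok)), "CDS has")
})
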