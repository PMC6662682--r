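test_that("scan_sites finds planted sites with strand and offset", {
  # 60 nt CDS with GAAGAC planted at offset 21
  base <- synth_cds(20, seed = 42)
  s <- plant_site(base, BBSI, 21, "+")
  hits <- scan_sites(s)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$enzyme, "BbsI")
  expect_identical(hits$strand, "+")
  expect_identical(hits$start, 21L)
  expect_identical(hits$overlapped_codons[[1]], 8:9)
  # no BsaI site anywhere
  expect_identical(nrow(scan_sites(s, list(BSAI))), 0L)
  # a GAGACC occurrence is a minus-strand BsaI hit
  s2 <- plant_site(base, BSAI, 24, "-")
  h2 <- scan_sites(s2, list(BSAI))
  expect_identical(h2$strand, "-")
  expect_identical(h2$start, 24L)
})

test_that("scan_sites agrees with a naive both-strand search", {
  set.seed(23)
  for (i in 1:25) {
    n_sites <- sample(0:3, 1)
    s <- if (n_sites == 0) synth_cds(120, seed = i)
         else synth_cds_with_sites(120, n_sites, seed = i,
                                   require_fixable = FALSE)$sequence
    expect_identical(scan_keys(scan_sites(s)), naive_scan(s))
  }
})

test_that("propose_silent_fix matches a brute-force search over synonyms", {
  set.seed(5)
  usage <- codon_usage("e_coli")
  for (i in 1:10) {
    fx <- synth_cds_with_sites(120, 1, seed = 100 + i)
    s <- as.character(fx$sequence)
    hit <- scan_sites(s)[1, ]
    fix <- propose_silent_fix(s, hit, usage)
    # oracle: enumerate every synonymous single-codon substitution in the
    # overlapped codons; keep destroyers that add no new site; max freq
    before <- scan_keys(scan_sites(s))
    key <- paste(hit$enzyme, hit$strand, hit$start, sep = ":")
    best <- NULL
    for (ci in hit$overlapped_codons[[1]]) {
      old <- substr(s, 3 * ci - 2, 3 * ci)
      for (cand in synonymous_codons(translate_dna(old))) {
        if (cand == old || usage_fraction(usage, cand) < 0.05) next
        trial <- paste0(substr(s, 1, 3 * ci - 3), cand,
                        substr(s, 3 * ci + 1, nchar(s)))
        after <- scan_keys(scan_sites(trial))
        if (key %in% after || !all(after %in% setdiff(before, key))) next
        fr <- usage_fraction(usage, cand)
        if (is.null(best) || fr > best$fr) best <- list(ci = ci, fr = fr)
      }
    }
    expect_false(is.null(best))
    expect_equal(fix$usage_freq, best$fr)
    # translation invariance of the proposed fix
    fixed <- gatemut:::replace_codon(s, fix$codon_index, fix$new_codon)
    expect_identical(translate_dna(fixed), translate_dna(s))
    # the fix removes the hit and strictly decreases the site count
    expect_false(key %in% scan_keys(scan_sites(fixed)))
    expect_lt(nrow(scan_sites(fixed)), nrow(scan_sites(s)))
  }
})

test_that("a site is undomesticatable when no usable synonym destroys it", {
  fx <- synth_cds_with_sites(100, 1, seed = 77)
  hit <- scan_sites(fx$sequence)[1, ]
  # no synonymous codon clears the usage threshold -> no candidate remains
  expect_error(propose_silent_fix(fx$sequence, hit, min_fraction = 1.01),
               "undomesticatable")
  # a hit that only overlaps codons without destroying synonyms (here:
  # restricted to a distant Met codon) is likewise unfixable
  s <- as.character(fx$sequence)
  met <- which(strsplit(translate_dna(s), "")[[1]] == "M")
  met <- met[met != 1][1]
  if (!is.na(met)) {
    hit$overlapped_codons <- I(list(met))
    expect_error(propose_silent_fix(s, hit), "undomesticatable")
  }
})

test_that("domesticate removes all sites, preserves protein, idempotent", {
  clean <- synth_cds(150, seed = 9)
  res0 <- domesticate(clean)
  expect_identical(as.character(res0$sequence), as.character(clean))
  expect_identical(nrow(res0$fixes), 0L)

  fx <- synth_cds_with_sites(150, 2, seed = 13)
  res <- domesticate(fx$sequence)
  expect_identical(nrow(res$fixes), 2L)
  expect_identical(nrow(scan_sites(res$sequence)), 0L)
  expect_identical(translate_dna(res$sequence), translate_dna(fx$sequence))
  # idempotence
  res2 <- domesticate(res$sequence)
  expect_identical(as.character(res2$sequence), as.character(res$sequence))
  expect_identical(nrow(res2$fixes), 0L)
})

test_that("domestication properties hold over random planted fixtures", {
  for (i in 1:30) {
    n_sites <- 1 + i %% 3
    fx <- synth_cds_with_sites(140, n_sites, seed = 1000 + i)
    res <- domesticate(fx$sequence)
    expect_identical(nrow(scan_sites(res$sequence)), 0L)
    expect_identical(translate_dna(res$sequence),
                     translate_dna(fx$sequence))
  }
})

test_that("fixes tables round-trip through CSV and JSON", {
  fx <- synth_cds_with_sites(120, 1, seed = 21)
  res <- domesticate(fx$sequence)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_fixes(res$fixes, csv)
  write_fixes(res$fixes, js)
  back <- read.csv(csv, stringsAsFactors = FALSE)
  expect_identical(back$new_codon, res$fixes$new_codon)
  expect_identical(
    jsonlite::read_json(js, simplifyVector = TRUE)$codon_index,
    res$fixes$codon_index)
})
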