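# A reusable 5-site NDT design on a synthetic CDS, with its pooled trace
make_qqc_design <- function(seed = 5) {
  cds <- yfex_like(seed)
  mut <- mutation_spec(c(137, 143, 147, 232, 234), "saturation", "NDT")
  design_mutagenesis(cds, mut)
}

test_that("forward reads locate all randomized codons", {
  d <- make_qqc_design()
  path <- tempfile(fileext = ".ab1")
  synth_abif_pool(d$plan$mutated_template, path, seed = 42)
  tr <- read_abif(path)
  pos <- locate_randomized_positions(tr, d)
  expect_length(pos, 5L)
  expect_true(all(vapply(pos, length, integer(1)) == 3L))
  # positions point at the codon starts in reference coordinates (the
  # synthetic read covers the full insert, offset 0)
  expect_identical(pos[["137"]], as.integer(3 * 136 + 1:3))
})

test_that("reverse reads map to the same codons as forward reads", {
  d <- make_qqc_design()
  fwd <- tempfile(fileext = ".ab1"); rev <- tempfile(fileext = ".ab1")
  synth_abif_pool(d$plan$mutated_template, fwd, seed = 7, noise_sd = 0)
  synth_abif_pool(d$plan$mutated_template, rev, seed = 7, noise_sd = 0,
                  direction = "reverse")
  tf <- qqc_analysis(fwd, d, "forward")
  tb <- qqc_analysis(rev, d, "reverse")
  expect_identical(tf$codon_index, tb$codon_index)
  expect_identical(tf$offset, tb$offset)
  for (b in c("A", "C", "G", "T"))
    expect_true(all(abs(tf[[b]] - tb[[b]]) <= 0.01))
})

test_that("unrelated reads are rejected", {
  d <- make_qqc_design()
  other <- as.character(synth_cds(299, seed = 99))
  path <- tempfile(fileext = ".ab1")
  synth_abif_pool(other, path, seed = 1)
  expect_error(locate_randomized_positions(read_abif(path),
                                           d$plan$mutated_template,
                                           design = d),
               "does not match")
})

test_that("NDT pools produce the expected per-offset distributions", {
  d <- make_qqc_design()
  path <- tempfile(fileext = ".ab1")
  fx <- synth_abif_pool(d$plan$mutated_template, path, seed = 42,
                        noise_sd = 0.1)
  tab <- qqc_analysis(path, d)
  expect_identical(nrow(tab), 15L)
  expect_true(all(abs(tab$A + tab$C + tab$G + tab$T - 1) < 1e-6))
  # offset 3 of NDT is invariant T
  o3 <- tab[tab$offset == 3, ]
  expect_true(all(o3$T == 1 & o3$A == 0 & o3$C == 0 & o3$G == 0))
  # offset 2 (D = A/G/T) is near one third each, C near zero
  o2 <- tab[tab$offset == 2, ]
  expect_true(all(abs(o2$A - 1/3) < 0.05))
  expect_true(all(abs(o2$G - 1/3) < 0.05))
  expect_true(all(abs(o2$T - 1/3) < 0.05))
  expect_true(all(o2$C == 0))
  # recovery against the generator's ground truth within 0.05 TV
  for (i in seq_len(nrow(tab))) {
    truth <- fx$truth[fx$truth$codon_index == tab$codon_index[i] &
                        fx$truth$offset == tab$offset[i], ]
    tv <- 0.5 * sum(abs(unlist(tab[i, c("A", "C", "G", "T")]) -
                          unlist(truth[, c("A", "C", "G", "T")])))
    expect_lt(tv, 0.05)
  }
})

test_that("total-variation divergence scores are correct and bounded", {
  expect_equal(compare_to_degeneracy(c(.25, .25, .25, .25), "N"), 0)
  expect_equal(compare_to_degeneracy(c(0, 0, 0, 1), "N"), 0.75)
  expect_equal(compare_to_degeneracy(c(A = 1/3, C = 0, G = 1/3, T = 1/3),
                                     "D"), 0)
  set.seed(2)
  for (i in 1:50) {
    p <- stats::runif(4); p <- p / sum(p)
    tv <- compare_to_degeneracy(p, "N")
    expect_gte(tv, 0); expect_lte(tv, 0.75)
  }
  expect_error(compare_to_degeneracy(c(.5, .5, 0, 0), "X"), "unknown")
})

test_that("the QQC report writes consistent CSV and figure files", {
  d <- make_qqc_design()
  path <- tempfile(fileext = ".ab1")
  synth_abif_pool(d$plan$mutated_template, path, seed = 42)
  tab <- qqc_analysis(path, d)
  prefix <- tempfile()
  paths <- render_qqc_report(tab, prefix)
  expect_true(file.exists(paths[["csv"]]))
  expect_true(file.exists(paths[["png"]]))
  back <- read.csv(paths[["csv"]])
  expect_equal(back$A + back$C + back$G + back$T, rep(1, nrow(back)),
               tolerance = 1e-6)
  # CSV rendering is deterministic
  prefix2 <- tempfile()
  render_qqc_report(tab, prefix2)
  expect_identical(readLines(paste0(prefix, ".csv")),
                   readLines(paste0(prefix2, ".csv")))
})
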