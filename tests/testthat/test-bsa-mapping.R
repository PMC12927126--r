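# SNP-index, divergence, filtering, smoothing, peak and candidate ranking.

test_that("snp_index is the alternative-allele read fraction", {
  expect_equal(snp_index(10, 20), 2 / 3)
  expect_equal(snp_index(0, 28), 1)
  expect_equal(snp_index(28, 0), 0)
  expect_true(is.na(snp_index(0, 0)))     # zero depth: undefined marker
  expect_error(snp_index(-1, 5), "non-negative")
})

test_that("snp_index_div is the summed absolute divergence with known bounds", {
  m <- theoretical_model()
  expect_identical(snp_index_div(1 / 3, 1, m), 0)        # causal expectation
  expect_equal(snp_index_div(0.5, 0.5, m), 2 / 3)
  expect_equal(snp_index_div(1, 1, m), 2 / 3)
  expect_error(snp_index_div(1.2, 0.5, m), "\\[0, 1\\]")

  # bounds and monotonicity over a grid: DIV in [0, 5/3]; fixing the MP
  # index, DIV is non-increasing as the WP index approaches 1/3
  grid <- expand.grid(wp = seq(0, 1, by = 0.05), mp = seq(0, 1, by = 0.05))
  d <- snp_index_div(grid$wp, grid$mp, m)
  expect_true(all(d >= 0 & d <= 5 / 3 + 1e-12))
  for (mp in c(0, 0.5, 1)) {
    wp_below <- seq(0, 1 / 3, by = 0.01)     # approaching theo from below
    expect_true(all(diff(snp_index_div(wp_below, rep(mp, length(wp_below)), m)) <= 1e-12))
    wp_above <- seq(1, 1 / 3, by = -0.01)    # and from above
    expect_true(all(diff(snp_index_div(wp_above, rep(mp, length(wp_above)), m)) <= 1e-12))
  }
})

test_that("score_markers applies the strict divergence threshold and depth floor", {
  # depths engineered to hit DIV values 0.10, 0.32, 0.34, 0.50 at the
  # default theoretical model are awkward; assert the strict '<' rule on the
  # divergence directly, then the scoring path on constructed depths
  m <- theoretical_model()
  divs <- c(0.10, 0.32, 0.34, 0.50)
  expect_identical(divs < m$div_threshold, c(TRUE, TRUE, FALSE, FALSE))

  ad <- rbind(c(20, 10, 0, 30),    # causal-like: WP 1/3, MP 1 -> DIV 0
              c(15, 15, 15, 15),   # het background -> DIV 2/3
              c(0, 30, 0, 30),     # fixed background -> DIV 2/3
              c(2, 0, 10, 20))     # WP depth 2 < min_depth -> excluded
  scored <- score_markers(markers_from_depths(ad), m)
  expect_equal(nrow(scored), 3)
  expect_identical(attr(scored, "n_excluded"), 1L)
  expect_equal(scored$snp_index_div[1], 0)
  expect_true(scored$passes_filter[1])
  expect_equal(scored$snp_index_div[2:3], rep(2 / 3, 2))
  expect_identical(scored$passes_filter[2:3], c(FALSE, FALSE))

  # a marker sitting exactly on the threshold is rejected (strict <)
  exact <- markers_from_depths(rbind(c(20, 10, 20, 10)))  # wp=mp=1/3, DIV=2/3...
  s2 <- score_markers(exact, theoretical_model(div_threshold = 2 / 3))
  expect_false(s2$passes_filter[1])

  expect_warning(score_markers(markers_from_depths(rbind(c(1, 0, 1, 0)))),
                 "no scorable")
})

test_that("score_markers agrees with a brute-force reimplementation", {
  set.seed(123)
  n <- 1000
  ad <- cbind(sample(0:60, n, TRUE), sample(0:60, n, TRUE),
              sample(0:60, n, TRUE), sample(0:60, n, TRUE))
  m <- theoretical_model(min_depth = 1)
  scored <- score_markers(markers_from_depths(ad), m)
  kept <- (ad[, 1] + ad[, 2]) >= 1 & (ad[, 3] + ad[, 4]) >= 1
  oracle_wp <- ad[kept, 2] / (ad[kept, 1] + ad[kept, 2])
  oracle_mp <- ad[kept, 4] / (ad[kept, 3] + ad[kept, 4])
  oracle_div <- abs(oracle_wp - 1 / 3) + abs(oracle_mp - 1)
  expect_equal(scored$snp_index_wp, oracle_wp, tolerance = 1e-12)
  expect_equal(scored$snp_index_mp, oracle_mp, tolerance = 1e-12)
  expect_equal(scored$snp_index_div, oracle_div, tolerance = 1e-12)
})

test_that("candidate chromosome is the argmax of filtered-marker counts", {
  mk <- data.table::data.table(
    chrom = c(rep("chr1", 2), rep("chr5", 40), rep("chr7", 3)),
    passes_filter = TRUE)
  expect_identical(select_candidate_chromosome(mk), "chr5")
  expect_identical(select_candidate_chromosome(
    data.table::data.table(chrom = "chr3", passes_filter = TRUE)), "chr3")
  # documented tie-break: first chromosome in order of appearance
  tie <- data.table::data.table(chrom = c(rep("chr1", 5), rep("chr2", 5)),
                                passes_filter = TRUE)
  expect_identical(select_candidate_chromosome(tie), "chr1")
  expect_error(select_candidate_chromosome(
    data.table::data.table(chrom = character(), passes_filter = logical())),
    "no filtered")
})

test_that("tricube smoothing matches its definition and finds tent peaks", {
  # constants are preserved; single points are their own smooth
  expect_equal(smooth_track(c(10, 20, 30), c(2, 2, 2), 15), rep(2, 3))
  expect_equal(smooth_track(5, 0.7, 100), 0.7)

  # brute-force oracle of the tricube Nadaraya-Watson formula
  brute <- function(x, v, h) {
    vapply(seq_along(x), function(i) {
      d <- abs(x - x[i]) / h
      w <- ifelse(d < 1, (1 - d^3)^3, 0)
      sum(w * v) / sum(w)
    }, numeric(1))
  }
  set.seed(33)
  x <- sort(sample(1:10000, 200))
  v <- runif(200)
  expect_equal(smooth_track(x, v, 1500), brute(x, v, 1500), tolerance = 1e-12)
  # output bounded by the input range
  sm <- smooth_track(x, v, 800)
  expect_true(all(sm >= min(v) - 1e-12 & sm <= max(v) + 1e-12))

  # symmetric tent over evenly spaced positions peaks at the center
  xs <- seq(0, 100, by = 10)
  tent <- 50 - abs(xs - 50)
  sm_tent <- smooth_track(xs, tent, 35)
  expect_equal(xs[which.max(sm_tent)], 50)
  expect_equal(locate_peak(xs, sm_tent), 50)

  expect_error(smooth_track(c(3, 1, 2), 1:3, 10), "sorted")
})

test_that("locate_peak takes the first maximum", {
  expect_equal(locate_peak(c(10, 20, 30), c(0.2, 0.9, 0.4)), 20)
  expect_equal(locate_peak(c(10, 20, 30), c(0.5, 0.5, 0.5)), 10)
})

test_that("candidate ranking demands MP homozygosity and MODERATE/HIGH impact", {
  mk <- data.table::data.table(
    chrom = "chr1",
    pos = c(500000L, 100000L, 0L) + 1000000L,
    ref = "C", alt = "T",
    snp_index_wp = 1 / 3, snp_index_mp = c(1.0, 1.0, 0.9),
    snp_index_div = 0.01, passes_filter = TRUE,
    effect = c("stop_gained", "missense", "stop_gained"),
    impact = c("HIGH", "MODERATE", "HIGH"),
    gene_id = c("gA", "gB", "gC"),
    hgvs_c = NA_character_, hgvs_p = NA_character_)
  ranked <- rank_candidates(mk, peak_position = 1000000L,
                            homozygosity_tolerance = 0)
  # C excluded (not fully homozygous); B closer than A
  expect_identical(ranked$gene_id, c("gB", "gA"))

  # with tolerance, C re-enters and wins on distance
  ranked2 <- rank_candidates(mk, 1000000L, homozygosity_tolerance = 0.1)
  expect_identical(ranked2$gene_id[1], "gC")

  # equidistant candidates: HIGH sorts before MODERATE
  mk2 <- data.table::copy(mk)[1:2]
  mk2$pos <- c(1100000L, 900000L)
  ranked3 <- rank_candidates(mk2, 1000000L)
  expect_identical(ranked3$impact, c("HIGH", "MODERATE"))

  # markers without annotation count as MODIFIER and drop out, quietly
  noann <- data.table::data.table(
    chrom = "chr1", pos = 1L, ref = "C", alt = "T", snp_index_wp = 1 / 3,
    snp_index_mp = 1, snp_index_div = 0, passes_filter = TRUE,
    ann = NA_character_)
  expect_message(out <- rank_candidates(noann, 1L), "no candidate")
  expect_equal(nrow(out), 0)
})
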