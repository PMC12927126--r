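# The synthetic EMS-mutagenesis / pooled-sequencing generator.

test_that("generate_reference honours lengths, composition and seed", {
  ref <- generate_reference(c(chr1 = 100), 0.5, rng_seed = 1)
  expect_s4_class(ref, "DNAStringSet")
  expect_equal(unname(Biostrings::width(ref)), 100)
  expect_named(as.character(ref), "chr1")

  # gc_content 0 forces AT-only sequence; near-0 boundary is legal
  at_only <- as.character(generate_reference(c(chr1 = 10, chr2 = 10), 0,
                                             rng_seed = 3))
  expect_true(all(!grepl("[GC]", at_only)))

  # realized GC fraction lies in a 99% binomial interval around the target
  # (z = 2.576, n = 50,000)
  s <- as.character(generate_reference(c(chr1 = 50000), 0.47, rng_seed = 7))
  gc_obs <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / 50000
  half <- 2.576 * sqrt(0.47 * 0.53 / 50000)
  expect_gt(gc_obs, 0.47 - half)
  expect_lt(gc_obs, 0.47 + half)

  # reproducible under a fixed seed
  expect_identical(as.character(generate_reference(c(chr1 = 500), 0.4, 42)),
                   as.character(generate_reference(c(chr1 = 500), 0.4, 42)))
  expect_error(generate_reference(c(chr1 = 0)), "length")
})

test_that("draw_ems_mutations follows the EMS substitution spectrum", {
  ref <- generate_reference(c(chr1 = 50000, chr2 = 50000), 0.47, rng_seed = 5)

  # bias 1: every mutation is a G->A or C->T transition at a G/C site
  mut <- draw_ems_mutations(ref, 500, gc_to_at_bias = 1, rng_seed = 2)
  expect_equal(nrow(mut), 500)
  expect_true(all((mut$ref == "G" & mut$alt == "A") |
                    (mut$ref == "C" & mut$alt == "T")))

  # zero mutations -> empty table
  expect_equal(nrow(draw_ems_mutations(ref, 0)), 0)

  # ref alleles always match the reference base; positions distinct and
  # sorted within chromosome
  seqs <- as.character(ref)
  expect_true(all(substring(seqs[mut$chrom], mut$pos, mut$pos) == mut$ref))
  expect_false(any(duplicated(mut[, c("chrom", "pos")])))
  expect_true(all(tapply(mut$pos, mut$chrom, function(p) !is.unsorted(p))))

  # realized transition fraction within a 99% binomial interval of the bias
  mut9 <- draw_ems_mutations(ref, 10000, gc_to_at_bias = 0.9, rng_seed = 9)
  frac <- mean((mut9$ref == "G" & mut9$alt == "A") |
                 (mut9$ref == "C" & mut9$alt == "T"))
  half <- 2.576 * sqrt(0.9 * 0.1 / 10000)
  expect_gt(frac, 0.9 - half)
  expect_lt(frac, 0.9 + half)

  # demanding more mutations than available sites errors
  tiny <- generate_reference(c(chr1 = 20), 0.5, rng_seed = 1)
  expect_error(draw_ems_mutations(tiny, 50), "sites")
})

test_that("M2 families segregate 1:2:1 with a fully recessive phenotype", {
  fam <- simulate_m2_family(50000, rng_seed = 11)
  # phenotype is a deterministic function of genotype (recessivity)
  expect_true(all((fam$phenotype == "mutant") == (fam$genotype == "mut_hom")))
  # mutant fraction converges to 1/4 (99% binomial interval)
  half <- 2.576 * sqrt(0.25 * 0.75 / 50000)
  expect_lt(abs(mean(fam$phenotype == "mutant") - 0.25), half)
  # heterozygote fraction among wild-type kernels converges to 2/3
  wt <- fam[fam$phenotype == "wild_type"]
  expect_lt(abs(mean(wt$genotype == "het") - 2 / 3), 0.01)
  expect_error(simulate_m2_family(0), "n_kernels")
})

test_that("expected pool allele frequencies match brute-force gamete enumeration", {
  expect_equal(expected_pool_allele_frequency("MP", 0), 1)
  expect_equal(expected_pool_allele_frequency("WP", 0), 1 / 3)
  expect_equal(expected_pool_allele_frequency("MP", 0.25), 0.75)
  expect_equal(expected_pool_allele_frequency("WP", 0.5), 0.5)

  # oracle: enumerate the 16 ordered F2 gamete pairs; gametes (causal, marker)
  # with coupling-phase frequencies
  enumerate <- function(pool, r) {
    gam <- list(c(1, 1), c(0, 0), c(1, 0), c(0, 1))      # (a?, m?)
    pr <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
    num <- 0; den <- 0
    for (i in 1:4) for (j in 1:4) {
      p <- pr[i] * pr[j]
      mutant <- gam[[i]][1] == 1 && gam[[j]][1] == 1
      in_pool <- if (pool == "MP") mutant else !mutant
      if (in_pool) {
        den <- den + p
        num <- num + p * (gam[[i]][2] + gam[[j]][2]) / 2
      }
    }
    num / den
  }
  for (r in c(0, 0.1, 0.25, 0.4, 0.5)) {
    expect_equal(expected_pool_allele_frequency("MP", r), enumerate("MP", r),
                 tolerance = 1e-12)
    expect_equal(expected_pool_allele_frequency("WP", r), enumerate("WP", r),
                 tolerance = 1e-12)
  }
  expect_error(expected_pool_allele_frequency("WP", 0.6), "0.5")
})

test_that("pooled depth sampling conserves depth and respects error model", {
  # fixed homozygous-mutant pool without error never yields reference reads
  for (i in 1:20) {
    obs <- simulate_pool_counts(dosages = rep(2L, 30), mean_depth = 40,
                                error_rate = 0, rng_seed = i)
    expect_identical(unname(obs["ad_ref"]), 0L)
  }
  # zero mean depth gives (0, 0)
  expect_identical(unname(simulate_pool_counts(dosages = rep(1L, 10),
                                               mean_depth = 0, rng_seed = 1)),
                   c(0L, 0L))
  # Monte-Carlo: mean alt fraction at frequency 0.5 within a 99% interval
  set.seed(99)
  fr <- replicate(10000, {
    o <- simulate_pool_counts(allele_frequency = 0.5, mean_depth = 30,
                              error_rate = 0.001)
    if (sum(o) == 0) NA_real_ else o["ad_alt"] / sum(o)
  })
  se <- sd(fr, na.rm = TRUE) / sqrt(sum(!is.na(fr)))
  expect_lt(abs(mean(fr, na.rm = TRUE) - 0.5), 2.576 * se + 1e-4)
  expect_error(simulate_pool_counts(dosages = integer()), "empty pool")
})

test_that("marker-level experiment reproduces segregation, spectrum and linkage", {
  sim <- simulate_bsa_experiment(toy_config(seed = 21))
  mk <- sim$markers
  expect_equal(nrow(mk), 600)
  # conservation: depths are consistent per pool by construction
  expect_true(all(mk$ad_ref_wp >= 0 & mk$ad_alt_wp >= 0 &
                    mk$ad_ref_mp >= 0 & mk$ad_alt_mp >= 0))
  # spectrum: transition fraction near the configured bias
  frac <- mean((mk$ref == "G" & mk$alt == "A") | (mk$ref == "C" & mk$alt == "T"))
  expect_lt(abs(frac - 0.98), 2.576 * sqrt(0.98 * 0.02 / 600) + 0.01)
  # causal marker present, annotated with the requested effect
  causal <- mk[mk$chrom == sim$truth$chromosome & mk$pos == sim$truth$position]
  expect_equal(nrow(causal), 1)
  expect_false(is.na(causal$ann))
  expect_identical(parse_ann_field(causal$ann)$effect_class, "missense")
  # determinism: identical config and seed give identical markers
  sim2 <- simulate_bsa_experiment(toy_config(seed = 21))
  expect_identical(sim$markers, sim2$markers)
})

test_that("empirical MP allele frequency at a linked marker tracks 1 - r", {
  # linkage oracle: average the realized MP gamete frequency over many draws
  # at fixed recombination fractions and compare with the closed form
  set.seed(7)
  for (r in c(0, 0.1, 0.3, 0.5)) {
    draws <- replicate(4000, {
      g <- emsmap:::draw_pool_gametes(r, wp_het = 20L, wp_wt = 10L, mp_n = 30L)
      g$mp_alt / 60
    })
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - expected_pool_allele_frequency("MP", r)),
              2.576 * se + 1e-3)
  }
  # and the WP side against the conditional expectation with known pool
  # composition: E[f_wp] = (k_het (1 - r) + (k_het + 2 k_wt) r) / (2 n)
  for (r in c(0, 0.2, 0.5)) {
    draws <- replicate(4000, {
      g <- emsmap:::draw_pool_gametes(r, wp_het = 20L, wp_wt = 10L, mp_n = 30L)
      g$wp_alt / 60
    })
    expected <- (20 * (1 - r) + (20 + 20) * r) / 60
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - expected), 2.576 * se + 1e-3)
  }
})

test_that("file-backed datasets are complete, consistent and byte-reproducible", {
  cfg <- toy_config(seed = 31, effect = "start_lost")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds <- suppressMessages(build_dataset(cfg, d1))
  expect_true(all(file.exists(unlist(ds$paths))))

  # truth sidecar records the causal spec
  truth <- data.table::fread(ds$paths$truth)
  expect_identical(truth$chromosome, "chrB")
  expect_identical(truth$effect, "start_lost")
  expect_identical(truth$hgvs_c, "c.3G>A")
  expect_identical(truth$hgvs_p, "p.M1?")

  # VCF round trip reproduces the marker table
  mk <- suppressMessages(read_pooled_vcf(ds$paths$vcf))
  expect_identical(mk$pos, ds$markers$pos)
  expect_identical(mk$ad_alt_wp, ds$markers$ad_alt_wp)
  expect_identical(mk$ad_ref_mp, ds$markers$ad_ref_mp)

  # effect round trip: GFF3 + FASTA recover the requested causal class
  gms <- read_gene_models(ds$paths$gff3)
  fa <- Biostrings::readDNAStringSet(ds$paths$fasta)
  names(fa) <- sub(" .*", "", names(fa))
  causal <- ds$markers[ds$markers$is_causal == TRUE]
  ann <- classify_effect(gms[[1]], fa,
                         list(chrom = causal$chrom, pos = causal$pos,
                              ref = causal$ref, alt = causal$alt))
  expect_identical(ann$effect_class, "start_lost")
  expect_identical(ann$hgvs_p, "p.M1?")

  # byte-identical reruns under the same seed
  ds2 <- suppressMessages(build_dataset(cfg, d2))
  for (f in c("fasta", "gff3", "vcf", "truth")) {
    expect_identical(readLines(ds$paths[[f]]), readLines(ds2$paths[[f]]))
  }
})
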