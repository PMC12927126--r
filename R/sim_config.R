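#' Simulation configuration for a pooled-sequencing mapping experiment
#'
#' Bundles and validates the parameters of the synthetic EMS-mutagenesis /
#' bulked-segregant experiment.  The defaults describe the study design the
#' simulator emulates, at desk scale: a 10 x 20 Mb genome carrying 20,000
#' EMS-induced SNPs with a 98% G:C->A:T transition bias, one recessive
#' causal SNP inside a gene body, an M2 ear segregating 3:1, phenotype
#' pools of 30 kernels each, 30x mean pooled depth and a 0.1% per-read
#' miscall rate.
#'
#' @param chromosome_lengths Named integer vector, chromosome -> length (bp).
#' @param n_mutations Total number of induced SNPs (including the causal one).
#' @param gc_to_at_bias Fraction of mutations that are G:C->A:T transitions.
#' @param gc_content Genome GC fraction used for reference/base sampling.
#' @param causal_spec List with `chromosome`, `position`, `effect` (one of
#'   `"missense"`, `"stop_gained"`, `"start_lost"`, `"synonymous"`) and
#'   optionally `strand` for the causal gene.
#' @param pool_size_wp,pool_size_mp Kernels per phenotype pool (default 30).
#' @param family_size Kernels on the simulated segregating M2 ear.
#' @param mean_depth Expected pooled sequencing depth per site (Poisson mean).
#' @param error_rate Per-read allele miscall probability.
#' @param fixed_fraction Fraction of background EMS SNPs fixed homozygous in
#'   the M1 (pool allele frequency 1 in both pools); the rest are
#'   heterozygous in the M1 and segregate (expected frequency 1/2 in an
#'   unselected pool).
#' @param bp_per_cM Physical-to-genetic scaling for the Haldane linkage map.
#' @param rng_seed Integer seed making the experiment reproducible.
#' @return An object of class `sim_config`.
#' @seealso [simulate_bsa_experiment()], [build_dataset()]
#' @export
sim_config <- function(chromosome_lengths = stats::setNames(rep(20e6, 10),
                                                            paste0("chr", 1:10)),
                       n_mutations = 20000,
                       gc_to_at_bias = 0.98,
                       gc_content = 0.47,
                       causal_spec = list(chromosome = "chr5",
                                          position = 10e6,
                                          effect = "missense"),
                       pool_size_wp = 30,
                       pool_size_mp = 30,
                       family_size = 300,
                       mean_depth = 30,
                       error_rate = 0.001,
                       fixed_fraction = 0.1,
                       bp_per_cM = 1e6,
                       rng_seed = 1) {
  chromosome_lengths <- round(chromosome_lengths)
  if (is.null(names(chromosome_lengths)) || any(!nzchar(names(chromosome_lengths)))) {
    stop("chromosome_lengths must be a named vector")
  }
  if (any(chromosome_lengths <= 0)) stop("all chromosome lengths must be > 0")
  if (n_mutations < 0 || n_mutations > sum(chromosome_lengths)) {
    stop("n_mutations must be between 0 and the total genome length")
  }
  for (p in c(gc_to_at_bias = gc_to_at_bias, error_rate = error_rate,
              fixed_fraction = fixed_fraction)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must lie in (0, 1)")
  if (pool_size_wp < 1 || pool_size_mp < 1) stop("pool sizes must be >= 1")
  if (family_size < pool_size_wp + pool_size_mp) {
    stop("family_size must be at least the summed pool sizes")
  }
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  if (bp_per_cM <= 0) stop("bp_per_cM must be > 0")
  causal_spec$effect <- match.arg(causal_spec$effect,
                                  c("missense", "stop_gained", "start_lost",
                                    "synonymous"))
  causal_spec$strand <- causal_spec$strand %||% "+"
  if (!causal_spec$chromosome %in% names(chromosome_lengths)) {
    stop("causal chromosome ", causal_spec$chromosome,
         " is not in chromosome_lengths")
  }
  causal_spec$position <- as.integer(causal_spec$position)
  if (causal_spec$position < 1 ||
      causal_spec$position > chromosome_lengths[[causal_spec$chromosome]]) {
    stop("causal position lies outside its chromosome")
  }
  structure(list(chromosome_lengths = chromosome_lengths,
                 n_mutations = as.integer(n_mutations),
                 gc_to_at_bias = gc_to_at_bias,
                 gc_content = gc_content,
                 causal_spec = causal_spec,
                 pool_size_wp = as.integer(pool_size_wp),
                 pool_size_mp = as.integer(pool_size_mp),
                 family_size = as.integer(family_size),
                 mean_depth = mean_depth,
                 error_rate = error_rate,
                 fixed_fraction = fixed_fraction,
                 bp_per_cM = bp_per_cM,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d chromosome(s), %.1f Mb total\n",
    "  %d EMS SNPs, G:C->A:T bias %.2f, fixed fraction %.2f\n",
    "  causal: %s:%d (%s, %s strand)\n",
    "  pools WP/MP: %d/%d kernels of a %d-kernel ear; depth %.0fx, error %.2g\n",
    "  linkage: %.0f bp/cM (Haldane); seed %d\n"),
    length(x$chromosome_lengths), sum(x$chromosome_lengths) / 1e6,
    x$n_mutations, x$gc_to_at_bias, x$fixed_fraction,
    x$causal_spec$chromosome, x$causal_spec$position, x$causal_spec$effect,
    x$causal_spec$strand, x$pool_size_wp, x$pool_size_mp, x$family_size,
    x$mean_depth, x$error_rate, x$bp_per_cM, x$rng_seed))
  invisible(x)
}
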