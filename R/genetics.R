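## Mendelian expectation calculators: segregation ratios for self and
## allelism-test crosses, and the mutant-yield estimator.

CROSS_TYPES <- c("self_heterozygote", "het_x_het_allelic",
                 "het_x_het_nonallelic")

#' Expected mutant fraction of a cross
#'
#' Fraction of offspring expected to show the recessive mutant phenotype:
#' selfing a heterozygote gives 1/4 (the 3:1 ear); crossing heterozygous
#' carriers of two *allelic* mutations also gives 1/4 (compound
#' heterozygotes are mutant); crossing carriers of mutations in two
#' *different* genes gives 0, since no offspring is homozygous at either
#' locus.
#'
#' @param cross_type One of `"self_heterozygote"`, `"het_x_het_allelic"`,
#'   `"het_x_het_nonallelic"`.
#' @return Expected mutant fraction in \[0, 1\].
#' @export
expected_mutant_fraction <- function(cross_type) {
  cross_type <- match.arg(cross_type, CROSS_TYPES)
  switch(cross_type,
         self_heterozygote = 1 / 4,
         het_x_het_allelic = 1 / 4,
         het_x_het_nonallelic = 0)
}

#' Simulate progeny phenotypes of a cross
#'
#' Gamete-level simulation of the crosses handled by
#' [expected_mutant_fraction()], assuming full recessivity and penetrance.
#' For the non-allelic cross each parent is heterozygous at its own locus
#' and wild-type homozygous at the other, so no offspring can be mutant.
#'
#' @param cross_type Cross type, as in [expected_mutant_fraction()].
#' @param n_progeny Number of offspring to draw.
#' @param rng_seed Optional integer seed.
#' @return Character vector of phenotypes (`"wild_type"` / `"mutant"`).
#' @export
simulate_cross_progeny <- function(cross_type, n_progeny, rng_seed = NULL) {
  cross_type <- match.arg(cross_type, CROSS_TYPES)
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  maybe_seed(rng_seed)
  if (cross_type %in% c("self_heterozygote", "het_x_het_allelic")) {
    ## each parent transmits its mutant allele with probability 1/2; the
    ## offspring is mutant iff it receives a mutant allele from both (for
    ## the allelic cross this is a mutant compound heterozygote)
    from_p1 <- rbinom(n_progeny, 1L, 0.5)
    from_p2 <- rbinom(n_progeny, 1L, 0.5)
    mutant <- from_p1 == 1L & from_p2 == 1L
  } else {
    ## locus 1: parent 1 is Aa, parent 2 AA -> offspring never aa;
    ## locus 2: parent 1 BB, parent 2 Bb -> offspring never bb
    a_dosage <- rbinom(n_progeny, 1L, 0.5) + 0L  # parent 2 contributes no a
    b_dosage <- rbinom(n_progeny, 1L, 0.5) + 0L  # parent 1 contributes no b
    mutant <- a_dosage == 2L | b_dosage == 2L
  }
  ifelse(mutant, "mutant", "wild_type")
}

#' Estimate the mutant yield of a mutagenesis campaign
#'
#' Expected number of recessive kernel mutants recovered from `n_ears`
#' mutagenized-pollination ears:
#' `n_ears * seeds_per_ear * survival_ratio * pollination_success *
#' mutant_ratio`.  The raw product is reported together with its truncated
#' (floor) integer value.
#'
#' @param seeds_per_ear Mean M1 seeds per mutagenized ear.
#' @param survival_ratio Fraction of M1 plants surviving to flowering.
#' @param mutant_ratio Fraction of self-pollinated M2 ears segregating a
#'   kernel mutant.
#' @param pollination_success Fraction of surviving plants successfully
#'   self-pollinated (default 1/2).
#' @param n_ears Number of mutagenized ears (default 100).
#' @return List with `raw` (the product) and `mutants` (floor integer).
#' @examples
#' estimate_mutant_yield(3.3, 0.40, 0.20)  # raw 13.2 -> 13 mutants
#' @export
estimate_mutant_yield <- function(seeds_per_ear, survival_ratio, mutant_ratio,
                                  pollination_success = 0.5, n_ears = 100) {
  stopifnot(seeds_per_ear >= 0, n_ears >= 0)
  for (p in c(survival_ratio, mutant_ratio, pollination_success)) {
    if (p < 0 || p > 1) stop("ratios must lie in [0, 1]")
  }
  raw <- n_ears * seeds_per_ear * survival_ratio * pollination_success *
    mutant_ratio
  list(raw = raw, mutants = as.integer(floor(raw)))
}
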