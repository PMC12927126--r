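---
title: "Mapping EMS-induced recessive mutations with pooled-sequencing BSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping EMS-induced recessive mutations with pooled-sequencing BSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsmap)
```

## The mapping problem

Ethyl methanesulfonate (EMS) mutagenesis of pollen is a fast way to build
large collections of recessive mutants in maize and other cereals. A single
mutagenized gamete carries thousands of induced point mutations, strongly
biased toward G:C→A:T transitions, and a mutant recovered in the M2
generation typically owes its phenotype to exactly one of them. Because all
induced SNPs ride in on the same gamete, they double as mapping markers:
crossing to a different ecotype is unnecessary, which avoids heterosis and
segregation of unrelated polymorphisms.

For a fully recessive single-gene kernel mutant, a selfed heterozygous M1
ear segregates wild-type : mutant kernels 3:1. Two pools are built from one
segregating ear — a wild-type pool (WP) and a mutant pool (MP), each with
at least 30 kernels — and sequenced to roughly 30×. `emsmap` starts from the
variant table of that experiment (VCF with per-sample allele depths, or a
GATK VariantsToTable-style TSV) and localizes the causal mutation.

## The statistic

For each biallelic SNP and each pool the **SNP-index** is the
alternative-allele read fraction,

$$\mathrm{SNPindex} = \frac{\mathrm{AD}_{alt}}{\mathrm{AD}_{ref} + \mathrm{AD}_{alt}}.$$

At the causal locus every MP kernel is homozygous mutant, so the expected
MP index is 1. WP kernels are the non-mutant residue of a 1:2:1 genotype
distribution — 2 heterozygotes for every homozygous wild type — so the
expected WP index is 1/3. The per-marker divergence from these theoretical
values is

$$\mathrm{DIV} = \left|\,\mathrm{SNPindex}_{WP} - \tfrac13\,\right| +
  \left|\,\mathrm{SNPindex}_{MP} - 1\,\right|,$$

zero at the causal marker in expectation. Markers with `DIV < 1/3` (strict
inequality) are retained as trait-associated. An unlinked marker that is
heterozygous in the M1 has expected index 1/2 in both pools and therefore
expected divergence $1/6 + 1/2 = 2/3$; a marker fixed in the M1 has index 1
in both pools, again with divergence $2/3 + 0 = 2/3$. Both background
classes sit a factor of two above the cutoff, which is what gives the filter
its discriminating power.

At a linked marker a recombination fraction $r$ from the causal locus, the
expected mutant-coupled allele frequency is $1-r$ in the MP and $(1+r)/3$
in the WP (`expected_pool_allele_frequency()`, derived by enumerating the
four coupling-phase gamete classes conditioned on kernel phenotype), so the
expected divergence grows as $4r/3$ and the filter retains markers out to
roughly $r = 1/4$.

The pipeline (`run_pipeline()`) then:

1. scores every marker with depth ≥ `min_depth` (default 5) in both pools
   (`score_markers()`);
2. picks the chromosome with the most filtered markers
   (`select_candidate_chromosome()`, ties to the first chromosome in
   order);
3. smooths the MP SNP-index of the filtered markers on that chromosome with
   a tricube-kernel Nadaraya–Watson average (`smooth_track()`), default
   bandwidth 2 Mb, and takes the position of the maximum as the peak
   (`locate_peak()`, ties to the smallest position);
4. ranks candidates (`rank_candidates()`): markers that are 100% homozygous
   in the MP (`snp_index_mp >= 1 - tolerance`, default tolerance 0) and
   whose predicted impact is MODERATE or HIGH, ordered by distance to the
   peak, then HIGH before MODERATE. When several candidates survive — as
   happens in practice when two genes near the peak each carry a qualifying
   mutation — all are reported; disambiguation is a job for allelism tests,
   not the statistic.

### Numerical choices

* The divergence threshold uses strict `<`, matching the printed rule.
* Zero-depth markers are undefined (the index is 0/0) and are excluded and
  counted; the `min_depth` floor of 5 reads per pool is a conservative,
  configurable default (`0` disables everything but the zero-depth rule).
* Smoothing was unspecified beyond "smoothed values"; tricube local
  averaging was chosen because it is the standard local-regression kernel,
  is bounded by the input range, and has one interpretable parameter (the
  bandwidth, exposed as a flag). The peak is computed on the smoothed MP
  index of filtered markers, the track a close-up inspection actually
  looks at; `peak_statistic = "div"` switches to inverted smoothed
  divergence.
* The candidate interval is reported as the span of filtered markers within
  one bandwidth of the peak — a descriptive bracket, not a confidence
  interval.

## The simulator

`simulate_bsa_experiment()` generates the full statistical structure the
analysis assumes, so every stage is testable without external data:

* **Mutation spectrum.** `n_mutations` distinct sites; with probability
  `gc_to_at_bias` (default 0.98) a mutation is a G→A or C→T transition at a
  G/C site, otherwise a uniformly chosen other substitution.
* **Segregation and pooling.** One ear of `family_size` kernels (default
  300) is drawn 1:2:1 from a selfed heterozygote; the mutant phenotype is
  fully recessive. Pools of 30 kernels per phenotype are sampled from the
  ear, so the WP carries the realized (not idealized) heterozygote count.
* **Linkage.** Physical distance to the causal locus converts to a
  recombination fraction via Haldane's map, $r = \frac12(1 - e^{-2d})$,
  with a configurable 1 Mb/cM scaling — a round maize-scale figure. All EMS
  alleles are in coupling with the causal allele. Markers on other
  chromosomes use $r = 1/2$ through the same machinery.
* **Background zygosity.** A configurable fraction of background SNPs
  (default `fixed_fraction = 0.1`, a modest share chosen a priori) is fixed
  homozygous in the M1; the rest are heterozygous and segregate. Both
  classes exercise the divergence filter from different directions.
* **Sequencing.** Per-site pool depth is Poisson with the configured mean
  (the standard shotgun-coverage model; only mean depths are usually
  reported), each read samples an allele at the pool's realized frequency
  and is flipped with probability `error_rate`.
* **Causal gene.** A two-exon toy gene (201 codons) is engineered around
  the causal position so that one EMS-type substitution yields the
  requested effect class; the variant is annotated through the package's
  own classifier and carried as a SnpEff-style ANN string.

Chromosome-scale sequence carries no information for the statistic beyond
the identity of the mutated base, so the default-scale generator draws
background reference alleles from the genome base composition —
statistically identical to placing sites on an i.i.d. random sequence — and
materializes actual sequence only for the causal gene locus, where codons
matter. `build_dataset()` is the file-backed variant: it materializes the
complete reference, patches in the engineered gene, and writes FASTA, GFF3,
a two-sample VCF (`GT:AD`) and a tab-separated truth sidecar, byte-identical
under a fixed seed; it is intended for toy genome sizes (the tests use a few
hundred kb).

### What the simulator does not emulate

Real pooled WGS adds mapping artefacts, depth heterogeneity (GC bias,
repeats), indels and multi-allelic sites, variant-caller filtering, and
marker–marker linkage disequilibrium beyond the causal-conditional
independence used here (each marker recombines independently given the
kernel's causal genotype; no crossover interference, no shared crossovers
between markers). Passing recovery tests on simulated data therefore
demonstrates the statistic and its implementation, not robustness to
caller- or alignment-level noise — which is why real-data SNP totals are
not a target the package tries to reproduce.

## The annotation mini-model

`classify_effect()` implements the minimal consequence model needed for
candidate ranking, over strand-aware CDS interval models
(`gene_model()`): any change in the initiator ATG is start-lost; a mutated
codon translating to stop is stop-gained; an unchanged amino acid is
synonymous; any other CDS change is missense. Impacts follow the SnpEff
convention (start-lost/stop-gained HIGH, missense MODERATE, synonymous LOW,
intronic/intergenic MODIFIER). HGVS strings use one-letter amino-acid codes
(`c.464C>T` / `p.P155L`, `p.Q118*`, `p.M1?`). The standard nuclear code is
assumed. Limitations, accepted deliberately: no splice-site model (intronic
variants are MODIFIER), no UTR or regulatory classes, no multi-transcript
genes, no indel consequences, and a SNP that disrupts the terminal stop
codon is reported as missense because the six-class vocabulary carries no
stop-lost.

## Mendelian calculators

`expected_mutant_fraction()` returns 1/4 for a selfed heterozygote and for
an allelism-test cross between carriers of two allelic mutations (compound
heterozygotes are mutant), and exactly 0 for carriers of mutations in two
different genes — the yardstick against which allelism-test ears are read.
`estimate_mutant_yield()` multiplies ears × seeds/ear × survival ×
pollination success (default 1/2) × mutant ratio and reports both the raw
product and its floor, the convention used when quoting whole mutants
(e.g. 3.3 seeds/ear × 40% survival × 1/2 × 20% over 100 ears → 13.2 → 13).

## Problem sizes and reproducibility

The default simulated experiment (10 × 20 Mb, 20,000 markers, pools of 30,
30× depth) runs in well under a second; the package's end-to-end checks use
20 seeded replicates of it, and smaller 3 × 300 kb / 600-marker
configurations for file-format round trips. Every stochastic entry point
takes an `rng_seed`, and a `sim_config` plus seed pins the entire
experiment, down to byte-identical output files from `build_dataset()`.
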