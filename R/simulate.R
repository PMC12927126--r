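## Synthetic EMS-mutagenesis / pooled-sequencing data generator.
##
## The generator reproduces the statistical structure the mapping analysis
## assumes: EMS-spectrum point mutations on a toy genome, Mendelian 1:2:1
## segregation of a recessive causal allele in a selfed-M1 ear, phenotype
## pooling, linkage between markers and the causal locus (Haldane map), and
## pooled short-read allele-depth sampling with sequencing error.

#' Generate a random reference genome
#'
#' Draws i.i.d. bases at the requested GC content, one sequence per
#' chromosome.
#'
#' @param chromosome_lengths Named vector of chromosome lengths (bp).
#' @param gc_content GC fraction in (0, 1); G and C (and A and T) are
#'   equiprobable within their class.  `gc_content = 0` is allowed and
#'   yields AT-only sequence.
#' @param rng_seed Optional integer seed.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
generate_reference <- function(chromosome_lengths, gc_content = 0.47,
                               rng_seed = NULL) {
  if (is.null(names(chromosome_lengths)) || any(!nzchar(names(chromosome_lengths)))) {
    stop("chromosome_lengths must be a named vector")
  }
  if (any(chromosome_lengths <= 0)) stop("all chromosome lengths must be > 0")
  if (gc_content < 0 || gc_content >= 1) stop("gc_content must lie in [0, 1)")
  maybe_seed(rng_seed)
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
  seqs <- vapply(chromosome_lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

## EMS substitution rules: with probability `bias` a mutation is a G->A or
## C->T transition (drawn at a G/C site); otherwise any other substitution.
ems_alt_for <- function(ref, is_transition) {
  n <- length(ref)
  alt <- character(n)
  tr <- is_transition & ref %in% c("G", "C")
  alt[tr] <- ifelse(ref[tr] == "G", "A", "T")
  for (i in which(!tr)) {
    choices <- setdiff(DNA_BASES, ref[i])
    ## "other" substitutions exclude the canonical EMS transition
    if (ref[i] == "G") choices <- setdiff(choices, "A")
    if (ref[i] == "C") choices <- setdiff(choices, "T")
    alt[i] <- sample(choices, 1L)
  }
  alt
}

#' Draw EMS-induced point mutations on a reference genome
#'
#' Samples `n_mutations` distinct genomic sites and assigns substitutions
#' following the EMS spectrum: with probability `gc_to_at_bias` a mutation
#' is a G->A or C->T transition at a G/C site, otherwise a uniformly chosen
#' other substitution at any remaining site.
#'
#' @param reference `DNAStringSet` or named character vector.
#' @param n_mutations Number of mutations (>= 0).
#' @param gc_to_at_bias Transition fraction in \[0, 1\].
#' @param rng_seed Optional integer seed.
#' @return `data.table` with columns `chrom`, `pos`, `ref`, `alt`, sorted by
#'   chromosome and position.
#' @export
draw_ems_mutations <- function(reference, n_mutations, gc_to_at_bias = 0.98,
                               rng_seed = NULL) {
  seqs <- as_ref_strings(reference)
  if (sum(nchar(seqs)) == 0L) stop("reference is empty")
  if (n_mutations < 0) stop("n_mutations must be >= 0")
  if (gc_to_at_bias < 0 || gc_to_at_bias > 1) {
    stop("gc_to_at_bias must lie in [0, 1]")
  }
  maybe_seed(rng_seed)
  empty <- data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character())
  if (n_mutations == 0L) return(empty)
  lens <- nchar(seqs)
  offsets <- cumsum(c(0, lens[-length(lens)]))
  names(offsets) <- names(seqs)
  total <- sum(lens)

  ## global index -> (chrom, pos)
  to_coord <- function(g) {
    ci <- findInterval(g - 1L, cumsum(lens), left.open = FALSE) + 1L
    data.table::data.table(chrom = names(seqs)[ci],
                           pos = as.integer(g - offsets[ci]))
  }
  gc_sites <- unlist(lapply(seq_along(seqs), function(i) {
    hits <- gregexpr("[GC]", seqs[[i]])[[1L]]
    if (hits[1L] == -1L) integer() else as.integer(hits) + offsets[[i]]
  }), use.names = FALSE)

  n_trans <- rbinom(1L, n_mutations, gc_to_at_bias)
  if (n_trans > length(gc_sites)) {
    stop("not enough G/C sites for the requested number of transitions")
  }
  trans_g <- if (n_trans > 0L) sample(gc_sites, n_trans) else integer()
  remaining <- n_mutations - n_trans
  other_pool <- total - n_trans
  if (remaining > other_pool) stop("n_mutations exceeds available sites")
  other_g <- integer()
  if (remaining > 0L) {
    ## rejection sampling of sites not already used (collision rate is tiny)
    used <- trans_g
    while (length(other_g) < remaining) {
      cand <- sample.int(total, remaining - length(other_g) + 10L,
                         replace = TRUE)
      cand <- setdiff(unique(cand), c(used, other_g))
      other_g <- c(other_g, head(cand, remaining - length(other_g)))
    }
  }
  g <- c(trans_g, other_g)
  coords <- to_coord(g)
  coords[, ref := substring(seqs[chrom], pos, pos)]
  is_trans <- c(rep(TRUE, n_trans), rep(FALSE, length(other_g)))
  coords[, alt := ems_alt_for(ref, is_trans)]
  coords[, chrom := factor(chrom, levels = names(seqs))]
  data.table::setorder(coords, chrom, pos)
  coords[, chrom := as.character(chrom)]
  coords[]
}

#' Simulate an M2 ear segregating for a recessive mutation
#'
#' Draws kernel genotypes at the causal locus as from a selfed heterozygous
#' M1 plant (1:2:1 wild-type-homozygote : heterozygote : mutant-homozygote);
#' the mutant phenotype is fully recessive, so a kernel is mutant iff it is
#' homozygous for the mutant allele, giving the expected 3:1 ear.
#'
#' @param n_kernels Number of kernels (>= 1).
#' @param rng_seed Optional integer seed.
#' @return `data.table` with columns `genotype` (factor `wt_hom`/`het`/
#'   `mut_hom`), `dosage` (0/1/2 mutant alleles) and `phenotype`
#'   (`wild_type`/`mutant`).
#' @export
simulate_m2_family <- function(n_kernels, rng_seed = NULL) {
  if (n_kernels < 1) stop("n_kernels must be >= 1")
  maybe_seed(rng_seed)
  dosage <- rbinom(n_kernels, 1L, 0.5) + rbinom(n_kernels, 1L, 0.5)
  genotype <- factor(c("wt_hom", "het", "mut_hom")[dosage + 1L],
                     levels = c("wt_hom", "het", "mut_hom"))
  data.table::data.table(
    genotype = genotype,
    dosage = as.integer(dosage),
    phenotype = ifelse(dosage == 2L, "mutant", "wild_type"))
}

#' Expected pooled allele frequency at a linked marker
#'
#' Infinite-pool expectation of the mutant-coupled allele frequency at a
#' marker a recombination fraction `r` away from the causal locus, in a
#' phenotype-selected pool of selfed-F2 kernels.  All EMS alleles are in
#' coupling on the mutagenized gamete, so the four M1 gamete classes are
#' a-m and A-M with frequency (1-r)/2 each, and a-M and A-m with frequency
#' r/2 each.  Conditioning on kernel phenotype gives 1 - r in the mutant
#' pool and (1 + r)/3 in the wild-type pool; at `r = 0` these are the
#' theoretical causal SNP-index values 1 and 1/3.
#'
#' @param pool_id `"WP"` or `"MP"`.
#' @param r Recombination fraction(s) in \[0, 0.5\].
#' @return Expected allele frequency in \[0, 1\].
#' @export
expected_pool_allele_frequency <- function(pool_id, r) {
  pool_id <- match.arg(toupper(pool_id), c("WP", "MP"))
  if (any(r < 0) || any(r > 0.5)) stop("r must lie in [0, 0.5]")
  if (pool_id == "MP") 1 - r else (1 + r) / 3
}

#' Sample pooled sequencing allele depths
#'
#' Simulates pooled whole-genome sequencing of one marker in one pool: the
#' total depth is Poisson with the configured mean, each read samples an
#' allele at the pool's realized alternative-allele frequency and is
#' miscalled (allele flipped) with probability `error_rate`.
#'
#' @param dosages Integer vector of per-kernel alternative-allele dosages
#'   (0, 1 or 2); the realized pool frequency is `sum(dosages) / (2 * n)`.
#'   Alternatively supply `allele_frequency` directly.
#' @param mean_depth Poisson mean of the total depth (>= 0).
#' @param error_rate Per-read miscall probability in \[0, 1\].
#' @param allele_frequency Realized pool alternative-allele frequency,
#'   bypassing `dosages`.
#' @param rng_seed Optional integer seed.
#' @return Named integer vector `c(ad_ref, ad_alt)`; the two counts always
#'   sum to the drawn total depth.
#' @export
simulate_pool_counts <- function(dosages = NULL, mean_depth = 30,
                                 error_rate = 0, allele_frequency = NULL,
                                 rng_seed = NULL) {
  if (is.null(allele_frequency)) {
    if (is.null(dosages) || length(dosages) == 0L) {
      stop("empty pool: supply kernel dosages or an allele frequency")
    }
    if (any(!dosages %in% 0:2)) stop("dosages must be 0, 1 or 2")
    allele_frequency <- sum(dosages) / (2 * length(dosages))
  }
  if (allele_frequency < 0 || allele_frequency > 1) {
    stop("allele_frequency must lie in [0, 1]")
  }
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0, 1]")
  maybe_seed(rng_seed)
  depth <- rpois(1L, mean_depth)
  p_alt <- allele_frequency * (1 - error_rate) +
    (1 - allele_frequency) * error_rate
  ad_alt <- rbinom(1L, depth, p_alt)
  c(ad_ref = depth - ad_alt, ad_alt = ad_alt)
}

## ---------------------------------------------------------------------------
## Toy causal gene construction

## per-effect design: target CDS position, reference codon, coding-strand
## ref/alt bases (all EMS-type G:C->A:T changes), chosen to mirror canonical
## HGVS outputs (p.P155L, p.Q118*, p.M1?, and a silent glycine change)
TOY_GENE_DESIGN <- list(
  missense    = list(cds_pos = 464L, codon_idx = 155L, codon = "CCA",
                     coding_ref = "C", coding_alt = "T"),
  stop_gained = list(cds_pos = 352L, codon_idx = 118L, codon = "CAG",
                     coding_ref = "C", coding_alt = "T"),
  start_lost  = list(cds_pos = 3L, codon_idx = 1L, codon = "ATG",
                     coding_ref = "G", coding_alt = "A"),
  synonymous  = list(cds_pos = 6L, codon_idx = 2L, codon = "GGC",
                     coding_ref = "C", coding_alt = "T")
)

TOY_GENE_N_CODONS <- 201L   # 200 residues + stop; CDS 603 bp
TOY_GENE_EXON1 <- 300L      # bp of CDS in the first exon
TOY_GENE_INTRON <- 150L     # intron length

#' Construct a toy causal gene around a genomic position
#'
#' Builds a two-exon protein-coding gene model whose CDS contains the
#' requested causal position at a coding position engineered so that a
#' single EMS-type substitution produces the requested effect class, and
#' returns the local reference sequence of the gene span plus the causal
#' variant and its annotation.
#'
#' @param chromosome Chromosome name.
#' @param chromosome_length Length of that chromosome (bp).
#' @param causal_position Genomic position of the causal SNP.
#' @param effect Requested effect class (`missense`, `stop_gained`,
#'   `start_lost` or `synonymous`).
#' @param strand Coding strand of the gene.
#' @param gene_id Gene identifier.
#' @return List with `model` ([gene_model()]), `ref` ([region_ref()] of the
#'   gene span), `causal` (list `chrom`, `pos`, `ref`, `alt`, `cds_pos`) and
#'   `annotation` (the [classify_effect()] result).
#' @export
make_toy_gene <- function(chromosome, chromosome_length, causal_position,
                          effect = "missense", strand = "+",
                          gene_id = "toy_gene_1") {
  design <- TOY_GENE_DESIGN[[match.arg(effect, names(TOY_GENE_DESIGN))]]
  total <- TOY_GENE_N_CODONS * 3L
  e1 <- TOY_GENE_EXON1
  e2 <- total - e1
  ## random sense codons, no internal stop; then pin start/stop/target codon
  sense <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], character())
  codons <- sample(sense, TOY_GENE_N_CODONS, replace = TRUE)
  codons[1L] <- "ATG"
  codons[TOY_GENE_N_CODONS] <- "TAA"
  codons[design$codon_idx] <- design$codon
  cds <- paste(codons, collapse = "")

  ## place the gene so that CDS position `cds_pos` falls on causal_position
  anchor <- gene_model(gene_id, chromosome, strand,
                       cbind(c(1L, e1 + TOY_GENE_INTRON + 1L),
                             c(e1, e1 + TOY_GENE_INTRON + e2)))
  delta <- cds_to_genomic(anchor, design$cds_pos) - 1L
  g0 <- as.integer(causal_position - delta)
  span_len <- total + TOY_GENE_INTRON
  if (g0 < 1L || g0 + span_len - 1L > chromosome_length) {
    stop("causal gene does not fit on ", chromosome,
         " at position ", causal_position)
  }
  gm <- gene_model(gene_id, chromosome, strand,
                   anchor$cds_intervals + g0 - 1L)

  ## fill the genomic span: CDS bases from the engineered coding sequence,
  ## intron bases random
  span <- rep(NA_character_, span_len)
  gpos <- cds_to_genomic(gm, seq_len(total))
  bases <- strsplit(cds, "")[[1L]]
  if (strand == "-") bases <- comp_base(bases)
  span[gpos - g0 + 1L] <- bases
  n_fill <- sum(is.na(span))
  span[is.na(span)] <- sample(DNA_BASES, n_fill, replace = TRUE)
  ref <- region_ref(chromosome, g0, paste(span, collapse = ""))

  causal <- list(
    chrom = chromosome,
    pos = as.integer(causal_position),
    ref = if (strand == "+") design$coding_ref else comp_base(design$coding_ref),
    alt = if (strand == "+") design$coding_alt else comp_base(design$coding_alt),
    cds_pos = design$cds_pos)
  annotation <- classify_effect(gm, ref, causal)
  stopifnot(identical(annotation$effect_class, match.arg(effect, names(TOY_GENE_DESIGN))))
  validate_gene_model(gm, ref)
  list(model = gm, ref = ref, causal = causal, annotation = annotation)
}

## ---------------------------------------------------------------------------
## Pool sampling machinery shared by simulate_bsa_experiment and build_dataset

## Vectorized draw of alternative-allele *gamete counts* for heterozygous
## (M1-het) markers given each WP kernel's causal genotype and the marker's
## recombination fraction with the causal locus.  Coupling phase: the mutant
## causal allele and every EMS marker allele rode in on the same gamete.
draw_pool_gametes <- function(r, wp_het, wp_wt, mp_n) {
  n <- length(r)
  ## WP: each het kernel has one causal-mutant gamete (marker alt w.p. 1-r)
  ## and one wild-type gamete (alt w.p. r); each wt-hom kernel two wild-type
  ## gametes.
  wp_alt <- rbinom(n, wp_het, 1 - r) + rbinom(n, wp_het + 2L * wp_wt, r)
  ## MP: all kernels are causal-homozygous: every gamete carries the causal
  ## allele, marker alt w.p. 1-r.
  mp_alt <- rbinom(n, 2L * mp_n, 1 - r)
  list(wp_alt = wp_alt, mp_alt = mp_alt)
}

## Given a marker table (chrom/pos/ref/alt) plus zygosity classes, draw the
## pooled read counts for both pools under the config's study conditions.
sample_pool_depths <- function(markers, config, wp_het, wp_wt) {
  n <- nrow(markers)
  causal <- config$causal_spec
  r <- rep(0.5, n)
  on_chr <- markers$chrom == causal$chromosome
  r[on_chr] <- haldane_r(abs(markers$pos[on_chr] - causal$position),
                         config$bp_per_cM)
  n_wp <- config$pool_size_wp
  n_mp <- config$pool_size_mp
  gam <- draw_pool_gametes(r, wp_het, wp_wt, n_mp)
  f_wp <- gam$wp_alt / (2 * n_wp)
  f_mp <- gam$mp_alt / (2 * n_mp)
  fixed <- markers$zygosity == "fixed"
  f_wp[fixed] <- 1
  f_mp[fixed] <- 1
  e <- config$error_rate
  dp_wp <- rpois(n, config$mean_depth)
  dp_mp <- rpois(n, config$mean_depth)
  ad_alt_wp <- rbinom(n, dp_wp, f_wp * (1 - e) + (1 - f_wp) * e)
  ad_alt_mp <- rbinom(n, dp_mp, f_mp * (1 - e) + (1 - f_mp) * e)
  markers[, `:=`(ad_ref_wp = dp_wp - ad_alt_wp, ad_alt_wp = ad_alt_wp,
                 ad_ref_mp = dp_mp - ad_alt_mp, ad_alt_mp = ad_alt_mp,
                 gt_wp = ifelse(fixed, "1/1", "0/1"),
                 gt_mp = ifelse(fixed | markers$is_causal, "1/1", "0/1"))]
  markers
}

## annotate markers that fall inside the toy gene span; returns ANN strings
annotate_gene_markers <- function(markers, gene) {
  span <- gene_span(gene$model)
  ann <- rep(NA_character_, nrow(markers))
  idx <- which(markers$chrom == gene$model$chromosome &
                 markers$pos >= span[1L] & markers$pos <= span[2L])
  for (i in idx) {
    a <- classify_effect(gene$model, gene$ref,
                         list(chrom = markers$chrom[i], pos = markers$pos[i],
                              ref = markers$ref[i], alt = markers$alt[i]))
    ann[i] <- format_ann(a, markers$alt[i])
  }
  ann
}

## draw phenotype pools from a segregating ear
draw_pools <- function(config) {
  fam <- simulate_m2_family(config$family_size)
  wt_idx <- which(fam$phenotype == "wild_type")
  mut_idx <- which(fam$phenotype == "mutant")
  if (length(wt_idx) < config$pool_size_wp ||
      length(mut_idx) < config$pool_size_mp) {
    stop("the simulated ear does not segregate enough kernels of each ",
         "phenotype to fill the pools; increase family_size")
  }
  wp <- sample(wt_idx, config$pool_size_wp)
  mp <- sample(mut_idx, config$pool_size_mp)
  list(family = fam,
       wp_het = sum(fam$genotype[wp] == "het"),
       wp_wt = sum(fam$genotype[wp] == "wt_hom"),
       mp_n = length(mp))
}

## ---------------------------------------------------------------------------

#' Simulate a complete pooled-sequencing mapping experiment (marker level)
#'
#' Generates the full data structure of an EMS bulked-segregant experiment
#' at marker level, without materializing chromosome-scale sequence:
#' background EMS SNPs receive reference alleles drawn from the genome base
#' composition (equivalent to sampling sites on an i.i.d. random sequence),
#' and actual sequence is constructed only for the causal gene locus, where
#' it is needed for effect annotation.  Use [build_dataset()] to emit
#' standard-format files for a (small) genome with fully materialized
#' sequence.
#'
#' @param config A [sim_config()].
#' @return List of class `bsa_sim` with elements `markers` (a `data.table`
#'   with per-pool allele depths and ANN strings for genic markers), `truth`
#'   (causal chromosome/position/alleles/effect and HGVS strings), `gene`
#'   (the toy causal gene) and `config`.
#' @export
simulate_bsa_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  causal <- config$causal_spec
  lens <- config$chromosome_lengths

  gene <- make_toy_gene(causal$chromosome, lens[[causal$chromosome]],
                        causal$position, causal$effect, causal$strand)
  pools <- draw_pools(config)

  ## background sites: distinct global indices, excluding the causal site
  n_bg <- config$n_mutations - 1L
  offsets <- cumsum(c(0, lens[-length(lens)]))
  names(offsets) <- names(lens)
  total <- sum(lens)
  causal_g <- offsets[[causal$chromosome]] + causal$position
  g <- sample.int(total - 1L, n_bg)
  g[g >= causal_g] <- g[g >= causal_g] + 1L
  ci <- findInterval(g - 1L, cumsum(lens)) + 1L
  bg <- data.table::data.table(chrom = names(lens)[ci],
                               pos = as.integer(g - offsets[ci]))

  ## EMS spectrum, sequence-free: transitions sit at G/C sites, other
  ## substitutions at sites drawn from the base composition
  is_trans <- runif(n_bg) < config$gc_to_at_bias
  gc <- config$gc_content
  comp <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ref <- character(n_bg)
  ref[is_trans] <- sample(c("G", "C"), sum(is_trans), replace = TRUE)
  ref[!is_trans] <- sample(DNA_BASES, sum(!is_trans), replace = TRUE,
                           prob = comp)
  ## sites landing inside the materialized gene span take its actual base
  span <- gene_span(gene$model)
  in_gene <- bg$chrom == causal$chromosome & bg$pos >= span[1L] &
    bg$pos <= span[2L]
  if (any(in_gene)) {
    ref[in_gene] <- vapply(bg$pos[in_gene], function(p) {
      ref_base(gene$ref, causal$chromosome, p)
    }, character(1))
    is_trans[in_gene] <- is_trans[in_gene] & ref[in_gene] %in% c("G", "C")
  }
  bg[, ref := ref]
  bg[, alt := ems_alt_for(ref, is_trans)]
  bg[, zygosity := ifelse(runif(.N) < config$fixed_fraction, "fixed", "het")]
  bg[, is_causal := FALSE]

  causal_row <- data.table::data.table(
    chrom = causal$chromosome, pos = gene$causal$pos, ref = gene$causal$ref,
    alt = gene$causal$alt, zygosity = "het", is_causal = TRUE)
  markers <- rbind(bg, causal_row)
  markers[, chrom := factor(chrom, levels = names(lens))]
  data.table::setorder(markers, chrom, pos)
  markers[, chrom := as.character(chrom)]

  markers <- sample_pool_depths(markers, config, pools$wp_het, pools$wp_wt)
  markers[, ann := annotate_gene_markers(markers, gene)]

  truth <- list(chromosome = causal$chromosome, position = gene$causal$pos,
                ref = gene$causal$ref, alt = gene$causal$alt,
                effect = gene$annotation$effect_class,
                impact = gene$annotation$impact,
                gene_id = gene$model$gene_id,
                cds_pos = gene$causal$cds_pos,
                hgvs_c = gene$annotation$hgvs_c,
                hgvs_p = gene$annotation$hgvs_p)
  structure(list(markers = markers[], truth = truth, gene = gene,
                 pools = pools[c("wp_het", "wp_wt", "mp_n")],
                 config = config),
            class = "bsa_sim")
}

#' Build a file-backed synthetic dataset
#'
#' Materializes a full reference genome, patches in the engineered causal
#' gene, draws EMS mutations from the actual sequence, simulates pooling and
#' pooled depths under the same machinery as [simulate_bsa_experiment()],
#' and writes standard-format files: reference FASTA, toy gene-model GFF3, a
#' two-sample (WP/MP) VCF v4.2 with `GT:AD`, and a tab-separated truth
#' sidecar.  Intended for toy genome sizes (tests use a few hundred kb);
#' outputs are byte-identical for identical configurations and seeds.
#'
#' @param config A [sim_config()] (use small chromosomes).
#' @param out_dir Output directory, created if needed.
#' @return List of class `bsa_sim` as from [simulate_bsa_experiment()], plus
#'   a `paths` element naming the written files.
#' @export
build_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)
  causal <- config$causal_spec
  lens <- config$chromosome_lengths

  reference <- as_ref_strings(generate_reference(lens, config$gc_content))
  gene <- make_toy_gene(causal$chromosome, lens[[causal$chromosome]],
                        causal$position, causal$effect, causal$strand)
  ## patch the gene's engineered span into the chromosome
  g0 <- gene$ref$start
  glen <- nchar(gene$ref$seq)
  chr_seq <- reference[[causal$chromosome]]
  substr(chr_seq, g0, g0 + glen - 1L) <- gene$ref$seq
  reference[[causal$chromosome]] <- chr_seq

  pools <- draw_pools(config)
  bg <- draw_ems_mutations(reference, config$n_mutations - 1L,
                           config$gc_to_at_bias)
  bg <- bg[!(chrom == causal$chromosome & pos == causal$position)]
  bg[, zygosity := ifelse(runif(.N) < config$fixed_fraction, "fixed", "het")]
  bg[, is_causal := FALSE]
  causal_row <- data.table::data.table(
    chrom = causal$chromosome, pos = gene$causal$pos, ref = gene$causal$ref,
    alt = gene$causal$alt, zygosity = "het", is_causal = TRUE)
  markers <- rbind(bg, causal_row)
  markers[, chrom := factor(chrom, levels = names(lens))]
  data.table::setorder(markers, chrom, pos)
  markers[, chrom := as.character(chrom)]

  markers <- sample_pool_depths(markers, config, pools$wp_het, pools$wp_wt)
  markers[, ann := annotate_gene_markers(markers, gene)]

  paths <- list(fasta = file.path(out_dir, "reference.fa"),
                gff3 = file.path(out_dir, "genes.gff3"),
                vcf = file.path(out_dir, "pools.vcf"),
                truth = file.path(out_dir, "truth.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference),
                              paths$fasta)
  write_gene_models(gene$model, paths$gff3)
  write_pooled_vcf(markers, paths$vcf, contigs = lens)

  truth <- list(chromosome = causal$chromosome, position = gene$causal$pos,
                ref = gene$causal$ref, alt = gene$causal$alt,
                effect = gene$annotation$effect_class,
                impact = gene$annotation$impact,
                gene_id = gene$model$gene_id,
                cds_pos = gene$causal$cds_pos,
                hgvs_c = gene$annotation$hgvs_c,
                hgvs_p = gene$annotation$hgvs_p)
  truth_dt <- data.table::as.data.table(truth)
  data.table::fwrite(truth_dt, paths$truth, sep = "\t")

  structure(list(markers = markers[], truth = truth, gene = gene,
                 pools = pools[c("wp_het", "wp_wt", "mp_n")],
                 config = config, paths = paths),
            class = "bsa_sim")
}
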