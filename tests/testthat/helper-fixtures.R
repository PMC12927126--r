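# Shared fixtures: small configurations and hand-built marker tables.

toy_config <- function(seed = 1, effect = "missense", ...) {
  sim_config(chromosome_lengths = c(chrA = 3e5, chrB = 3e5, chrC = 3e5),
             n_mutations = 600,
             causal_spec = list(chromosome = "chrB", position = 150000,
                                effect = effect),
             rng_seed = seed, ...)
}

# deterministic marker table from explicit depth quadruples
markers_from_depths <- function(ad, chrom = NULL, pos = NULL) {
  n <- nrow(ad)
  data.table::data.table(
    chrom = chrom %||% rep("chr1", n),
    pos = pos %||% seq_len(n) * 1000L,
    ref = rep("C", n), alt = rep("T", n),
    ad_ref_wp = ad[, 1], ad_alt_wp = ad[, 2],
    ad_ref_mp = ad[, 3], ad_alt_mp = ad[, 4],
    ann = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-exon plus-strand toy gene with a fully specified CDS, for
# annotation tests; cds is a character scalar of codons
single_exon_gene <- function(cds, chrom = "chr1", start = 101L,
                             strand = "+", flank = 20L) {
  stopifnot(nchar(cds) %% 3 == 0)
  L <- nchar(cds)
  gm <- gene_model("g1", chrom, strand, cbind(start, start + L - 1L))
  genomic <- if (strand == "+") cds else {
    paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]), collapse = "")
  }
  seq <- paste0(paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                      collapse = ""),
                genomic,
                paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                      collapse = ""))
  ref <- region_ref(chrom, start - flank, seq)
  list(model = gm, ref = ref)
}

# write a toy two-sample VCF; rows is a character vector of data lines
write_toy_vcf <- function(rows, path = tempfile(fileext = ".vcf"),
                          samples = c("WP", "MP"), format = "GT:AD") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}
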