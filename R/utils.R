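## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Haldane map function
#'
#' Converts a physical distance in base pairs to a recombination fraction
#' via Haldane's mapping function, r = 0.5 * (1 - exp(-2 d)), with d in
#' Morgans obtained from a constant physical-to-genetic scaling.
#'
#' @param distance_bp Physical distance in base pairs (vectorized).
#' @param bp_per_cM Base pairs per centiMorgan (default 1e6).
#' @return Recombination fraction(s) in \[0, 0.5).
#' @export
haldane_r <- function(distance_bp, bp_per_cM = 1e6) {
  stopifnot(all(distance_bp >= 0), bp_per_cM > 0)
  d_morgan <- distance_bp / (bp_per_cM * 100)
  0.5 * (1 - exp(-2 * d_morgan))
}

## complement of a character vector of single bases (or strings)
comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## translate a 3-base codon with the standard nuclear code ("*" = stop)
translate_codon <- function(codon) {
  stopifnot(nchar(codon) == 3L)
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("invalid codon: ", codon)
  aa
}

## coerce reference input (DNAStringSet / named character) to named character
as_ref_strings <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
  } else if (is.character(reference)) {
    out <- reference
  } else {
    stop("reference must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("reference sequences must be named by chromosome")
  }
  out
}

#' Reference window anchored at a genomic offset
#'
#' A lightweight container holding the sequence of one genomic region, used
#' when only a local window (for example a gene locus on an otherwise
#' unmaterialized chromosome) is available for annotation.
#'
#' @param chromosome Chromosome name.
#' @param start 1-based genomic position of the first base of `seq`.
#' @param seq Character scalar, the region sequence.
#' @return An object of class `region_ref`.
#' @export
region_ref <- function(chromosome, start, seq) {
  stopifnot(is.character(chromosome), length(chromosome) == 1L,
            start >= 1, is.character(seq), length(seq) == 1L)
  structure(list(chromosome = chromosome, start = as.integer(start),
                 seq = toupper(seq)),
            class = "region_ref")
}

## fetch a single reference base; reference is a region_ref, DNAStringSet or
## named character vector of chromosome sequences
ref_base <- function(reference, chromosome, position) {
  if (inherits(reference, "region_ref")) {
    if (chromosome != reference$chromosome) {
      stop("position is on ", chromosome, " but the reference window covers ",
           reference$chromosome)
    }
    off <- position - reference$start + 1L
    if (off < 1L || off > nchar(reference$seq)) {
      stop("position ", position, " lies outside the reference window")
    }
    return(substr(reference$seq, off, off))
  }
  seqs <- as_ref_strings(reference)
  if (!chromosome %in% names(seqs)) {
    stop("chromosome ", chromosome, " not present in the reference")
  }
  if (position < 1L || position > nchar(seqs[[chromosome]])) {
    stop("position ", position, " lies outside ", chromosome)
  }
  substr(seqs[[chromosome]], position, position)
}

## deterministic chromosome ordering: keep order of first appearance unless
## levels are supplied
chrom_levels <- function(chrom, levels = NULL) {
  levels %||% unique(chrom)
}

## set seed only when one is given; callers inside a seeded stream pass NULL
maybe_seed <- function(rng_seed) {
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  invisible(NULL)
}
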