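## Miniature strand-aware variant-effect annotation over toy gene models.
##
## A gene model is a set of non-overlapping CDS intervals on one strand of
## one chromosome; the classifier projects genomic SNPs into CDS space,
## reconstructs the affected codon from the reference sequence and assigns
## a SnpEff-style effect class / impact plus HGVS c. and p. strings.

EFFECT_CLASSES <- c("missense", "stop_gained", "start_lost", "synonymous",
                    "intronic", "intergenic")

IMPACT_OF_EFFECT <- c(
  missense    = "MODERATE",
  stop_gained = "HIGH",
  start_lost  = "HIGH",
  synonymous  = "LOW",
  intronic    = "MODIFIER",
  intergenic  = "MODIFIER"
)

## Sequence Ontology terms used in ANN strings <-> effect classes
SO_TERM_OF_EFFECT <- c(
  missense    = "missense_variant",
  stop_gained = "stop_gained",
  start_lost  = "start_lost",
  synonymous  = "synonymous_variant",
  intronic    = "intron_variant",
  intergenic  = "intergenic_region"
)

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals Two-column matrix or data.frame of 1-based closed
#'   genomic `[start, end]` CDS intervals (exons of the coding region).
#' @return An object of class `gene_model`.
#' @details Intervals must be non-overlapping and are stored sorted by
#'   genomic position; the total CDS length must be divisible by 3.  Whether
#'   the CDS actually starts with ATG and ends with a stop codon can only be
#'   checked against sequence, see [validate_gene_model()].
#' @export
gene_model <- function(gene_id, chromosome, strand, cds_intervals) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(chromosome), length(chromosome) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  ivl <- as.matrix(cds_intervals)
  if (ncol(ivl) != 2L) stop("cds_intervals must have two columns (start, end)")
  storage.mode(ivl) <- "integer"
  if (any(ivl[, 1L] > ivl[, 2L]) || any(ivl[, 1L] < 1L)) {
    stop("invalid CDS interval: need 1 <= start <= end")
  }
  ivl <- ivl[order(ivl[, 1L]), , drop = FALSE]
  if (nrow(ivl) > 1L && any(ivl[-1L, 1L] <= ivl[-nrow(ivl), 2L])) {
    stop("CDS intervals overlap")
  }
  total <- sum(ivl[, 2L] - ivl[, 1L] + 1L)
  if (total %% 3L != 0L) stop("total CDS length must be divisible by 3")
  colnames(ivl) <- c("start", "end")
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 cds_intervals = ivl, cds_length = total),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d CDS exon(s), %d bp CDS\n",
              x$gene_id, x$chromosome, min(x$cds_intervals[, "start"]),
              max(x$cds_intervals[, "end"]), x$strand,
              nrow(x$cds_intervals), x$cds_length))
  invisible(x)
}

gene_span <- function(gm) {
  c(min(gm$cds_intervals[, "start"]), max(gm$cds_intervals[, "end"]))
}

#' Check a gene model against reference sequence
#'
#' Verifies that the coding sequence implied by the model starts with ATG,
#' ends with a stop codon and contains no premature stop.
#'
#' @param gm A [gene_model()].
#' @param reference Reference sequence (`DNAStringSet`, named character
#'   vector, or [region_ref()]).
#' @return `gm`, invisibly; errors if the model is inconsistent.
#' @export
validate_gene_model <- function(gm, reference) {
  cds <- extract_cds_seq(gm, reference)
  if (substr(cds, 1L, 3L) != "ATG") {
    stop("CDS of ", gm$gene_id, " does not begin with ATG")
  }
  n <- nchar(cds)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aas <- vapply(codons, translate_codon, character(1))
  if (aas[length(aas)] != "*") {
    stop("CDS of ", gm$gene_id, " does not end with a stop codon")
  }
  if (any(aas[-length(aas)] == "*")) {
    stop("CDS of ", gm$gene_id, " contains a premature stop codon")
  }
  invisible(gm)
}

## coding-strand CDS sequence of a gene model
extract_cds_seq <- function(gm, reference) {
  pieces <- apply(gm$cds_intervals, 1L, function(iv) {
    paste(vapply(iv[1L]:iv[2L], function(p) {
      ref_base(reference, gm$chromosome, p)
    }, character(1)), collapse = "")
  })
  s <- paste(pieces, collapse = "")
  if (gm$strand == "-") s <- revcomp(s)
  s
}

#' Codon address of a CDS position
#'
#' Maps a 1-based coding-DNA position (the number in HGVS `c.` notation) to
#' its amino-acid residue index and position within the codon.
#'
#' @param cds_position 1-based CDS position(s).
#' @return A data.frame with columns `residue_index` and `codon_offset`
#'   (1, 2 or 3).
#' @examples
#' cds_position_to_codon(464)  # residue 155, offset 2
#' @export
cds_position_to_codon <- function(cds_position) {
  cds_position <- as.integer(cds_position)
  if (any(is.na(cds_position)) || any(cds_position < 1L)) {
    stop("cds_position must be a positive integer")
  }
  data.frame(residue_index = (cds_position - 1L) %/% 3L + 1L,
             codon_offset  = (cds_position - 1L) %% 3L + 1L)
}

## genomic positions of all CDS bases in coding order
cds_genomic_positions <- function(gm) {
  pos <- unlist(apply(gm$cds_intervals, 1L, function(iv) iv[1L]:iv[2L],
                      simplify = FALSE), use.names = FALSE)
  pos <- sort(pos)
  if (gm$strand == "-") pos <- rev(pos)
  pos
}

#' Project a genomic position into CDS coordinates
#'
#' @param gm A [gene_model()].
#' @param genomic_position 1-based genomic position(s) on the gene's
#'   chromosome.
#' @return Integer CDS position(s) (HGVS `c.` number); `NA` for positions
#'   outside the CDS ("non-coding").
#' @export
genomic_to_cds <- function(gm, genomic_position) {
  map <- cds_genomic_positions(gm)
  out <- match(as.integer(genomic_position), map)
  as.integer(out)
}

#' Project a CDS position onto the genome
#'
#' @param gm A [gene_model()].
#' @param cds_position 1-based CDS position(s).
#' @return Genomic position(s).
#' @export
cds_to_genomic <- function(gm, cds_position) {
  cds_position <- as.integer(cds_position)
  if (any(cds_position < 1L) || any(cds_position > gm$cds_length)) {
    stop("cds_position outside CDS (length ", gm$cds_length, ")")
  }
  cds_genomic_positions(gm)[cds_position]
}

#' Classify the coding effect of a SNP
#'
#' Assigns a SnpEff-style effect class, impact category and HGVS `c.`/`p.`
#' strings to a single-nucleotide variant, given a gene model and reference
#' sequence.  Any change within the initiator ATG is start-lost; a mutated
#' codon translating to a stop is stop-gained; an unchanged amino acid is
#' synonymous; any other CDS change is missense.  Positions inside the gene
#' span but outside CDS intervals are intronic; positions outside the span
#' are intergenic.
#'
#' @param gm A [gene_model()].
#' @param reference Reference sequence (`DNAStringSet`, named character, or
#'   [region_ref()] covering the gene).
#' @param variant List or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` (single bases, genomic strand).
#' @return An object of class `effect_annotation`: a list with
#'   `effect_class`, `impact`, `gene_id`, `hgvs_c`, `hgvs_p`.
#' @export
classify_effect <- function(gm, reference, variant) {
  v <- as.list(variant)
  stopifnot(!is.null(v$chrom), !is.null(v$pos), !is.null(v$ref), !is.null(v$alt))
  pos <- as.integer(v$pos)
  vref <- toupper(as.character(v$ref)); valt <- toupper(as.character(v$alt))
  if (!vref %in% DNA_BASES || !valt %in% DNA_BASES || vref == valt) {
    stop("variant must be a biallelic SNP with distinct single-base alleles")
  }
  if (v$chrom != gm$chromosome) {
    return(effect_annotation("intergenic", gm$gene_id, NA_character_,
                             NA_character_))
  }
  span <- gene_span(gm)
  if (pos < span[1L] || pos > span[2L]) {
    return(effect_annotation("intergenic", gm$gene_id, NA_character_,
                             NA_character_))
  }
  cpos <- genomic_to_cds(gm, pos)
  if (is.na(cpos)) {
    return(effect_annotation("intronic", gm$gene_id, NA_character_,
                             NA_character_))
  }
  genome_base <- ref_base(reference, gm$chromosome, pos)
  if (genome_base != vref) {
    stop(sprintf("reference allele mismatch at %s:%d: variant says %s, reference has %s",
                 gm$chromosome, pos, vref, genome_base))
  }
  ## alleles on the coding strand
  cref <- if (gm$strand == "+") vref else comp_base(vref)
  calt <- if (gm$strand == "+") valt else comp_base(valt)
  addr <- cds_position_to_codon(cpos)
  cds_pos_of_codon <- (addr$residue_index - 1L) * 3L + 1:3
  gpos <- cds_to_genomic(gm, cds_pos_of_codon)
  codon <- vapply(seq_len(3L), function(i) {
    b <- ref_base(reference, gm$chromosome, gpos[i])
    if (gm$strand == "-") comp_base(b) else b
  }, character(1))
  codon <- paste(codon, collapse = "")
  mut_codon <- codon
  substr(mut_codon, addr$codon_offset, addr$codon_offset) <- calt
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(mut_codon)
  hgvs_c <- sprintf("c.%d%s>%s", cpos, cref, calt)
  if (addr$residue_index == 1L) {
    cls <- "start_lost"; hgvs_p <- "p.M1?"
  } else if (aa_alt == "*" && aa_ref != "*") {
    cls <- "stop_gained"; hgvs_p <- sprintf("p.%s%d*", aa_ref, addr$residue_index)
  } else if (aa_alt == aa_ref) {
    cls <- "synonymous"; hgvs_p <- sprintf("p.%s%d%s", aa_ref, addr$residue_index, aa_alt)
  } else {
    ## includes stop-codon disruption, reported as missense (documented
    ## limitation; the six-class vocabulary has no stop_lost)
    cls <- "missense"; hgvs_p <- sprintf("p.%s%d%s", aa_ref, addr$residue_index, aa_alt)
  }
  effect_annotation(cls, gm$gene_id, hgvs_c, hgvs_p)
}

effect_annotation <- function(effect_class, gene_id, hgvs_c, hgvs_p,
                              impact = NULL) {
  effect_class <- match.arg(effect_class, EFFECT_CLASSES)
  structure(list(effect_class = effect_class,
                 impact = impact %||% unname(IMPACT_OF_EFFECT[effect_class]),
                 gene_id = gene_id, hgvs_c = hgvs_c, hgvs_p = hgvs_p),
            class = "effect_annotation")
}

#' @export
print.effect_annotation <- function(x, ...) {
  cat(sprintf("<effect_annotation> %s (%s) gene=%s %s|%s\n", x$effect_class,
              x$impact, x$gene_id, x$hgvs_c %||% ".", x$hgvs_p %||% "."))
  invisible(x)
}

#' Format an effect annotation as a SnpEff-style ANN string
#'
#' Produces the 16-field pipe-delimited ANN entry
#' (`Allele|Annotation|Impact|Gene_Name|Gene_ID|...|HGVS.c|HGVS.p|...`)
#' accepted by [parse_ann_field()].
#'
#' @param annotation An `effect_annotation`.
#' @param alt_allele The ALT allele the annotation refers to.
#' @return Character scalar.
#' @export
format_ann <- function(annotation, alt_allele) {
  stopifnot(inherits(annotation, "effect_annotation"))
  fields <- c(alt_allele,
              SO_TERM_OF_EFFECT[[annotation$effect_class]],
              annotation$impact,
              annotation$gene_id,
              annotation$gene_id,
              "transcript",
              paste0(annotation$gene_id, "_T001"),
              "protein_coding",
              "1/1",
              annotation$hgvs_c %||% "",
              annotation$hgvs_p %||% "",
              "", "", "", "", "")
  fields[is.na(fields)] <- ""
  paste(fields, collapse = "|")
}

#' Read toy gene models from a GFF3 file
#'
#' Builds [gene_model()] objects from the CDS features of a GFF3 file (one
#' model per gene, using the `Parent`-resolved gene identifier).
#'
#' @param path GFF3 file.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  gff <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features found in ", path)
  parent1 <- vapply(seq_len(nrow(cds)), function(i) {
    p <- unlist(cds$Parent[i])
    if (length(p)) p[1L] else as.character(cds$ID[i])
  }, character(1))
  gene_of <- sub("_T[0-9]+$", "", parent1)
  out <- lapply(split(seq_len(nrow(cds)), gene_of), function(idx) {
    sub <- cds[idx, , drop = FALSE]
    gene_model(gene_id = gene_of[idx[1L]],
               chromosome = as.character(sub$seqnames)[1L],
               strand = as.character(sub$strand)[1L],
               cds_intervals = cbind(sub$start, sub$end))
  })
  out
}

#' Write toy gene models to GFF3
#'
#' Emits gene, mRNA and CDS features for each model.
#'
#' @param gene_models List of [gene_model()] objects.
#' @param path Output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gene_models, path) {
  if (inherits(gene_models, "gene_model")) gene_models <- list(gene_models)
  lines <- c("##gff-version 3")
  for (gm in gene_models) {
    span <- gene_span(gm)
    tid <- paste0(gm$gene_id, "_T001")
    lines <- c(lines,
      sprintf("%s\temsmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              gm$chromosome, span[1L], span[2L], gm$strand, gm$gene_id),
      sprintf("%s\temsmap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              gm$chromosome, span[1L], span[2L], gm$strand, tid, gm$gene_id))
    ivl <- gm$cds_intervals
    ## GFF3 phase: bases to skip before the first full codon of each segment
    ord <- if (gm$strand == "+") seq_len(nrow(ivl)) else rev(seq_len(nrow(ivl)))
    done <- 0L
    phase <- integer(nrow(ivl))
    for (i in ord) {
      phase[i] <- (3L - done %% 3L) %% 3L
      done <- done + (ivl[i, "end"] - ivl[i, "start"] + 1L)
    }
    for (i in seq_len(nrow(ivl))) {
      lines <- c(lines,
        sprintf("%s\temsmap\tCDS\t%d\t%d\t.\t%s\t%d\tID=CDS:%s;Parent=%s",
                gm$chromosome, ivl[i, "start"], ivl[i, "end"], gm$strand,
                phase[i], tid, tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
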