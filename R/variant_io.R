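## Reading and writing the standard formats the pipeline touches: VCF with
## per-sample allele depths (via vcfR), GATK VariantsToTable-style TSV, and
## SnpEff-style ANN annotation strings.

#' Read a two-pool VCF with allele depths
#'
#' Parses a VCF v4.2 file containing the wild-type and mutant pool samples
#' and per-sample `AD` (allele depth) FORMAT fields into the marker table
#' used by the mapping functions.  Only biallelic SNP records are kept;
#' multi-allelic and indel lines are skipped and counted.  Gzipped input is
#' handled transparently.
#'
#' @param path VCF file (`.vcf` or `.vcf.gz`).
#' @param wp_sample,mp_sample Sample names of the wild-type and mutant pool
#'   (defaults `"WP"` / `"MP"`).
#' @return `data.table` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ad_ref_wp`, `ad_alt_wp`, `ad_ref_mp`, `ad_alt_mp`, `gt_wp`, `gt_mp`,
#'   `ann` (NA when the record has no ANN INFO entry); the number of skipped
#'   non-biallelic-SNP lines is attached as attribute `n_skipped` and
#'   reported with a message.
#' @export
read_pooled_vcf <- function(path, wp_sample = "WP", mp_sample = "MP") {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  empty <- data.table::data.table(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), ad_ref_wp = integer(), ad_alt_wp = integer(),
    ad_ref_mp = integer(), ad_alt_mp = integer(), gt_wp = character(),
    gt_mp = character(), ann = character())
  if (nrow(fix) == 0L) {
    data.table::setattr(empty, "n_skipped", 0L)
    return(empty)
  }
  samples <- colnames(vcf@gt)[-1L]
  for (s in c(wp_sample, mp_sample)) {
    if (!s %in% samples) {
      stop("pool sample '", s, "' not found in VCF (samples: ",
           paste(samples, collapse = ", "), ")")
    }
  }
  fmt <- vcf@gt[, "FORMAT"]
  no_ad <- !vapply(strsplit(fmt, ":"), function(f) "AD" %in% f, logical(1))
  if (any(no_ad)) {
    stop("AD missing from FORMAT at VCF data line ", which(no_ad)[1L])
  }
  keep <- fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message("read_pooled_vcf: skipped ", n_skipped,
            " non-biallelic-SNP record(s)")
  }
  if (!any(keep)) {
    data.table::setattr(empty, "n_skipped", n_skipped)
    return(empty)
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  parse_ad <- function(x, sample) {
    bad <- !grepl("^[0-9]+,[0-9]+$", x)
    if (any(bad)) {
      stop("malformed AD value '", x[which(bad)[1L]], "' for sample ", sample)
    }
    parts <- data.table::tstrsplit(x, ",", fixed = TRUE, type.convert = TRUE)
    list(ref = as.integer(parts[[1L]]), alt = as.integer(parts[[2L]]))
  }
  ad_wp <- parse_ad(ad[keep, wp_sample], wp_sample)
  ad_mp <- parse_ad(ad[keep, mp_sample], mp_sample)
  ann <- unname(vcfR::extract.info(vcf, element = "ANN")[keep])
  out <- data.table::data.table(
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep],
    ad_ref_wp = ad_wp$ref, ad_alt_wp = ad_wp$alt,
    ad_ref_mp = ad_mp$ref, ad_alt_mp = ad_mp$alt,
    gt_wp = unname(gt[keep, wp_sample]), gt_mp = unname(gt[keep, mp_sample]),
    ann = ann)
  data.table::setattr(out, "n_skipped", n_skipped)
  out
}

#' Read a VariantsToTable-style variant table
#'
#' Reads a tab-separated table in the layout produced by GATK's
#' VariantsToTable (columns `CHROM`, `POS`, `REF`, `ALT` plus per-sample
#' `<sample>.GT` and `<sample>.AD` columns, AD formatted `"ref,alt"`) into
#' the same marker table as [read_pooled_vcf()].
#'
#' @param path Tab-separated file (gzip transparently supported).
#' @param wp_sample,mp_sample Pool sample names used in the column headers.
#' @return `data.table` as for [read_pooled_vcf()].
#' @export
read_variants_table <- function(path, wp_sample = "WP", mp_sample = "MP") {
  if (!file.exists(path)) stop("file not found: ", path)
  ## dec = "." pinned so "ref,alt" AD strings are never read as decimals
  tab <- data.table::fread(path, sep = "\t", dec = ".",
                           colClasses = list(
                             character = c("CHROM", "REF", "ALT")))
  need <- c("CHROM", "POS", "REF", "ALT",
            paste0(wp_sample, c(".GT", ".AD")),
            paste0(mp_sample, c(".GT", ".AD")))
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  parse_ad <- function(x, col) {
    x <- as.character(x)
    bad <- !grepl("^[0-9]+,[0-9]+$", x)
    if (any(bad)) {
      stop("malformed AD value '", x[which(bad)[1L]], "' in column ", col)
    }
    parts <- data.table::tstrsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(parts[[1L]]), alt = as.integer(parts[[2L]]))
  }
  keep <- tab$REF %in% DNA_BASES & tab$ALT %in% DNA_BASES
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message("read_variants_table: skipped ", n_skipped,
            " non-biallelic-SNP row(s)")
  }
  tab <- tab[keep]
  ad_wp <- parse_ad(tab[[paste0(wp_sample, ".AD")]], paste0(wp_sample, ".AD"))
  ad_mp <- parse_ad(tab[[paste0(mp_sample, ".AD")]], paste0(mp_sample, ".AD"))
  out <- data.table::data.table(
    chrom = tab$CHROM, pos = as.integer(tab$POS), ref = tab$REF,
    alt = tab$ALT,
    ad_ref_wp = ad_wp$ref, ad_alt_wp = ad_wp$alt,
    ad_ref_mp = ad_mp$ref, ad_alt_mp = ad_mp$alt,
    gt_wp = as.character(tab[[paste0(wp_sample, ".GT")]]),
    gt_mp = as.character(tab[[paste0(mp_sample, ".GT")]]),
    ann = if ("ANN" %in% names(tab)) as.character(tab$ANN) else NA_character_)
  data.table::setattr(out, "n_skipped", n_skipped)
  out
}

#' Parse a SnpEff-style ANN field
#'
#' Splits the first (most severe) annotation entry of a pipe-delimited ANN
#' string into an [classify_effect()]-compatible `effect_annotation`.
#' Unknown effect terms are mapped to intergenic/MODIFIER with a warning.
#'
#' @param ann_string ANN INFO value (entries separated by `,`, subfields by
#'   `|`, per the SnpEff ANN specification).
#' @return An `effect_annotation`.
#' @export
parse_ann_field <- function(ann_string) {
  if (is.null(ann_string) || length(ann_string) != 1L || is.na(ann_string) ||
      !nzchar(ann_string)) {
    stop("empty ANN string")
  }
  first <- strsplit(ann_string, ",", fixed = TRUE)[[1L]][1L]
  fields <- strsplit(first, "|", fixed = TRUE)[[1L]]
  if (length(fields) < 11L) {
    stop("ANN entry has ", length(fields),
         " subfields; at least 11 are required")
  }
  term <- fields[2L]
  cls_map <- stats::setNames(names(SO_TERM_OF_EFFECT), SO_TERM_OF_EFFECT)
  if (term %in% names(cls_map)) {
    cls <- cls_map[[term]]
    impact <- fields[3L]
    if (!impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")) {
      impact <- IMPACT_OF_EFFECT[[cls]]
    }
  } else {
    warning("unknown effect term '", term, "'; treating as intergenic/MODIFIER")
    cls <- "intergenic"
    impact <- "MODIFIER"
  }
  blank_na <- function(x) if (!nzchar(x)) NA_character_ else x
  effect_annotation(cls, gene_id = blank_na(fields[5L]),
                    hgvs_c = blank_na(fields[10L]),
                    hgvs_p = blank_na(fields[11L]),
                    impact = impact)
}

#' Write a two-sample pooled VCF
#'
#' Emits the marker table as a VCF v4.2 file with `WP` and `MP` sample
#' columns carrying `GT:AD`, and ANN INFO entries where annotations are
#' present.
#'
#' @param markers Marker `data.table` (as produced by the simulator or the
#'   readers).
#' @param path Output file.
#' @param contigs Optional named vector of chromosome lengths for `##contig`
#'   header lines.
#' @param wp_sample,mp_sample Sample names to write.
#' @return `path`, invisibly.
#' @export
write_pooled_vcf <- function(markers, path, contigs = NULL,
                             wp_sample = "WP", mp_sample = "MP") {
  m <- data.table::as.data.table(markers)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=emsmap",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs))
    },
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank | HGVS.c | HGVS.p | cDNA.pos / cDNA.length | CDS.pos / CDS.length | AA.pos / AA.length | Distance | ERRORS / WARNINGS / INFO'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", wp_sample, mp_sample, sep = "\t"))
  gt_wp <- if ("gt_wp" %in% names(m)) m$gt_wp else "./."
  gt_mp <- if ("gt_mp" %in% names(m)) m$gt_mp else "./."
  ann <- if ("ann" %in% names(m)) m$ann else rep(NA_character_, nrow(m))
  info <- ifelse(is.na(ann), ".", paste0("ANN=", ann))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:AD\t%s:%d,%d\t%s:%d,%d",
                  m$chrom, m$pos, m$ref, m$alt, info,
                  gt_wp, m$ad_ref_wp, m$ad_alt_wp,
                  gt_mp, m$ad_ref_mp, m$ad_alt_mp)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a variant table in VariantsToTable layout
#'
#' Companion writer to [read_variants_table()]: emits `CHROM`, `POS`,
#' `REF`, `ALT`, per-pool `GT`/`AD` columns and an `ANN` column.
#'
#' @inheritParams write_pooled_vcf
#' @return `path`, invisibly.
#' @export
write_variants_table <- function(markers, path, wp_sample = "WP",
                                 mp_sample = "MP") {
  m <- data.table::as.data.table(markers)
  out <- data.table::data.table(
    CHROM = m$chrom, POS = m$pos, REF = m$ref, ALT = m$alt)
  out[[paste0(wp_sample, ".GT")]] <- if ("gt_wp" %in% names(m)) m$gt_wp else "./."
  out[[paste0(wp_sample, ".AD")]] <- sprintf("%d,%d", m$ad_ref_wp, m$ad_alt_wp)
  out[[paste0(mp_sample, ".GT")]] <- if ("gt_mp" %in% names(m)) m$gt_mp else "./."
  out[[paste0(mp_sample, ".AD")]] <- sprintf("%d,%d", m$ad_ref_mp, m$ad_alt_mp)
  if ("ann" %in% names(m)) out$ANN <- m$ann
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write the scored marker table
#'
#' Writes the per-marker table (allele depths, SNP-indices, divergence,
#' filter flag and parsed annotation fields) as a deterministic
#' tab-separated file ordered by chromosome then position.
#'
#' @param indexed_markers Output of [score_markers()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(indexed_markers, path) {
  m <- data.table::as.data.table(indexed_markers)
  m <- m[order(factor(chrom, levels = unique(chrom)), pos)]
  ann_fields <- lapply(m$ann, function(a) {
    if (is.na(a)) {
      list(effect = NA_character_, impact = NA_character_,
           gene_id = NA_character_, hgvs_c = NA_character_,
           hgvs_p = NA_character_)
    } else {
      p <- suppressWarnings(parse_ann_field(a))
      list(effect = p$effect_class, impact = p$impact, gene_id = p$gene_id,
           hgvs_c = p$hgvs_c, hgvs_p = p$hgvs_p)
    }
  })
  for (f in c("effect", "impact", "gene_id", "hgvs_c", "hgvs_p")) {
    m[[f]] <- vapply(ann_fields, function(x) x[[f]] %||% NA_character_,
                     character(1))
  }
  cols <- intersect(c("chrom", "pos", "ref", "alt", "ad_ref_wp", "ad_alt_wp",
                      "ad_ref_mp", "ad_alt_mp", "snp_index_wp",
                      "snp_index_mp", "snp_index_div", "passes_filter",
                      "effect", "impact", "gene_id", "hgvs_c", "hgvs_p"),
                    names(m))
  data.table::fwrite(m[, cols, with = FALSE], path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}
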