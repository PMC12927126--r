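## The core mapping computation: per-pool SNP-index, SNP-index.DIV against
## the theoretical causal-locus expectations, threshold filtering, candidate
## chromosome selection, kernel smoothing, peak localization and candidate
## ranking.

#' Theoretical model for a recessive single-gene trait
#'
#' Expected causal-locus SNP-index values for the two pools and the
#' divergence filter settings.  For a fully recessive single-gene mutation
#' mapped in selfed-F2 pools the causal marker is expected at SNP-index 1/3
#' in the wild-type pool (two heterozygous kernels for every homozygous
#' wild-type kernel) and 1 in the mutant pool, giving divergence 0.
#'
#' @param theo_wp Expected wild-type-pool SNP-index at the causal locus.
#' @param theo_mp Expected mutant-pool SNP-index at the causal locus.
#' @param div_threshold Markers with divergence strictly below this value
#'   are retained as trait-associated (default 1/3).
#' @param min_depth Minimum per-pool depth for a marker to be scored
#'   (default 5; 0 disables everything except the zero-depth rule).
#' @return An object of class `theoretical_model`.
#' @export
theoretical_model <- function(theo_wp = 1 / 3, theo_mp = 1,
                              div_threshold = 1 / 3, min_depth = 5) {
  stopifnot(theo_wp >= 0, theo_wp <= 1, theo_mp >= 0, theo_mp <= 1,
            div_threshold > 0, min_depth >= 0)
  structure(list(theo_wp = theo_wp, theo_mp = theo_mp,
                 div_threshold = div_threshold,
                 min_depth = as.integer(min_depth)),
            class = "theoretical_model")
}

#' Pooled SNP-index
#'
#' Fraction of reads carrying the alternative (mutant) allele:
#' `ad_alt / (ad_ref + ad_alt)`.  Markers with zero total depth are
#' undefined and return `NA`.
#'
#' @param ad_ref,ad_alt Non-negative reference/alternative allele depths
#'   (vectorized).
#' @return Numeric in \[0, 1\], `NA` where the total depth is zero.
#' @export
snp_index <- function(ad_ref, ad_alt) {
  if (any(ad_ref < 0, na.rm = TRUE) || any(ad_alt < 0, na.rm = TRUE)) {
    stop("allele depths must be non-negative")
  }
  total <- ad_ref + ad_alt
  ifelse(total == 0, NA_real_, ad_alt / total)
}

#' SNP-index divergence from the theoretical causal-locus values
#'
#' `|SNP-index.WP - theo_wp| + |SNP-index.MP - theo_mp|`; zero exactly at
#' the theoretical causal-marker indices, at most 5/3 for indices in
#' \[0, 1\] under the recessive defaults.
#'
#' @param idx_wp,idx_mp Pool SNP-indices in \[0, 1\] (vectorized).
#' @param model A [theoretical_model()].
#' @return Non-negative divergence values.
#' @export
snp_index_div <- function(idx_wp, idx_mp, model = theoretical_model()) {
  if (any(idx_wp < 0 | idx_wp > 1, na.rm = TRUE) ||
      any(idx_mp < 0 | idx_mp > 1, na.rm = TRUE)) {
    stop("SNP-index values must lie in [0, 1]")
  }
  abs(idx_wp - model$theo_wp) + abs(idx_mp - model$theo_mp)
}

#' Score markers: SNP-indices, divergence and filter flag
#'
#' Computes both pool SNP-indices, the divergence and the trait-association
#' flag (`snp_index_div < div_threshold`, strict inequality) for every
#' marker with at least `min_depth` reads in each pool; markers below the
#' depth floor (including zero-depth markers) are excluded and counted.
#'
#' @param variants Marker table with `ad_ref_wp`, `ad_alt_wp`, `ad_ref_mp`,
#'   `ad_alt_mp` columns (as from the readers or the simulator).
#' @param model A [theoretical_model()].
#' @return `data.table` of scored markers with columns `snp_index_wp`,
#'   `snp_index_mp`, `snp_index_div`, `passes_filter` appended; attributes
#'   `n_input` and `n_excluded` carry the bookkeeping.  A warning is issued
#'   when no marker is scorable.
#' @export
score_markers <- function(variants, model = theoretical_model()) {
  v <- data.table::as.data.table(variants)
  need <- c("ad_ref_wp", "ad_alt_wp", "ad_ref_mp", "ad_alt_mp")
  missing <- setdiff(need, names(v))
  if (length(missing)) {
    stop("variants lack required column(s): ", paste(missing, collapse = ", "))
  }
  n_input <- nrow(v)
  floor_depth <- max(model$min_depth, 1L)
  ok <- (v$ad_ref_wp + v$ad_alt_wp) >= floor_depth &
    (v$ad_ref_mp + v$ad_alt_mp) >= floor_depth
  out <- v[ok]
  if (nrow(out) == 0L) {
    warning("no scorable markers after the depth filter")
  }
  out[, snp_index_wp := snp_index(ad_ref_wp, ad_alt_wp)]
  out[, snp_index_mp := snp_index(ad_ref_mp, ad_alt_mp)]
  out[, snp_index_div := snp_index_div(snp_index_wp, snp_index_mp, model)]
  out[, passes_filter := snp_index_div < model$div_threshold]
  data.table::setattr(out, "n_input", n_input)
  data.table::setattr(out, "n_excluded", n_input - nrow(out))
  out[]
}

#' Select the candidate chromosome
#'
#' The chromosome carrying the largest number of filtered (trait-associated)
#' markers; ties are broken by chromosome order of appearance.
#'
#' @param scored Scored marker table from [score_markers()] (only rows with
#'   `passes_filter` are counted; a plain filtered table works too).
#' @return Chromosome name.
#' @export
select_candidate_chromosome <- function(scored) {
  s <- data.table::as.data.table(scored)
  if ("passes_filter" %in% names(s)) s <- s[passes_filter == TRUE]
  if (nrow(s) == 0L) stop("no filtered markers: no mapping signal")
  counts <- table(factor(s$chrom, levels = unique(s$chrom)))
  names(counts)[which.max(counts)]
}

#' Kernel-smooth a genomic track
#'
#' Tricube-kernel Nadaraya-Watson local averaging of per-marker values at
#' the marker positions themselves: for each position the smoothed value is
#' the weighted mean of all values within one bandwidth, with weights
#' `(1 - (d / h)^3)^3`.  The output is therefore bounded by the range of the
#' input values.
#'
#' @param positions Sorted (ascending) marker positions in bp.
#' @param values Values to smooth (same length).
#' @param bandwidth_bp Kernel half-width in bp (default 2 Mb).
#' @return Numeric vector of smoothed values at `positions`.
#' @export
smooth_track <- function(positions, values, bandwidth_bp = 2e6) {
  stopifnot(length(positions) == length(values), length(positions) >= 1L,
            bandwidth_bp > 0)
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  n <- length(positions)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- findInterval(positions[i] - bandwidth_bp, positions,
                       left.open = TRUE) + 1L
    hi <- findInterval(positions[i] + bandwidth_bp, positions,
                       left.open = TRUE)
    j <- lo:hi
    d <- abs(positions[j] - positions[i]) / bandwidth_bp
    w <- (1 - d^3)^3
    w[d >= 1] <- 0
    out[i] <- sum(w * values[j]) / sum(w)
  }
  out
}

#' Locate the peak of a smoothed track
#'
#' Position of the maximum smoothed value; ties are resolved to the
#' smallest position.
#'
#' @param positions Sorted marker positions.
#' @param smoothed_values Smoothed values at those positions.
#' @return Peak position (bp).
#' @export
locate_peak <- function(positions, smoothed_values) {
  stopifnot(length(positions) == length(smoothed_values),
            length(positions) >= 1L)
  positions[which.max(smoothed_values)]
}

#' Rank candidate causal mutations
#'
#' Applies the candidate rules to filtered markers on the candidate
#' chromosome: the marker must be (near-)homozygous in the mutant pool
#' (`snp_index_mp >= 1 - homozygosity_tolerance`; the default tolerance 0
#' demands 100% homozygosity) and its predicted impact must be MODERATE or
#' HIGH.  Surviving markers are ordered by ascending distance to the peak,
#' then HIGH before MODERATE.
#'
#' @param filtered_markers Filtered markers on the candidate chromosome
#'   (with `snp_index_mp`, `pos` and `ann` columns; markers without
#'   annotation count as MODIFIER and are dropped).
#' @param peak_position Peak position from [locate_peak()].
#' @param homozygosity_tolerance Allowed shortfall of `snp_index_mp` below 1.
#' @return `data.table` of candidates with parsed annotation columns and
#'   `distance_bp`; empty (with a message) when no marker qualifies.
#' @export
rank_candidates <- function(filtered_markers, peak_position,
                            homozygosity_tolerance = 0) {
  m <- data.table::as.data.table(filtered_markers)
  stopifnot(homozygosity_tolerance >= 0, homozygosity_tolerance <= 1)
  if (nrow(m) > 0L && !"impact" %in% names(m)) {
    parsed <- lapply(m$ann %||% rep(NA_character_, nrow(m)), function(a) {
      if (is.null(a) || is.na(a)) {
        list(effect = NA_character_, impact = "MODIFIER",
             gene_id = NA_character_, hgvs_c = NA_character_,
             hgvs_p = NA_character_)
      } else {
        p <- suppressWarnings(parse_ann_field(a))
        list(effect = p$effect_class, impact = p$impact, gene_id = p$gene_id,
             hgvs_c = p$hgvs_c, hgvs_p = p$hgvs_p)
      }
    })
    m[, effect := vapply(parsed, `[[`, character(1), "effect")]
    m[, impact := vapply(parsed, `[[`, character(1), "impact")]
    m[, gene_id := vapply(parsed, `[[`, character(1), "gene_id")]
    m[, hgvs_c := vapply(parsed, `[[`, character(1), "hgvs_c")]
    m[, hgvs_p := vapply(parsed, `[[`, character(1), "hgvs_p")]
  }
  keep <- m$snp_index_mp >= 1 - homozygosity_tolerance &
    m$impact %in% c("MODERATE", "HIGH")
  out <- m[keep]
  if (nrow(out) == 0L) {
    message("rank_candidates: no candidate mutation satisfies the rules")
    out[, distance_bp := numeric(0)]
    return(out[])
  }
  out[, distance_bp := abs(pos - peak_position)]
  data.table::setorderv(out, c("distance_bp"))
  out <- out[order(distance_bp, match(impact, c("HIGH", "MODERATE")))]
  out[]
}

#' Run the full mapping pipeline
#'
#' Scores all markers, selects the candidate chromosome, smooths the
#' mutant-pool SNP-index of the filtered markers on that chromosome,
#' locates the peak, reports a candidate interval (span of filtered markers
#' within one bandwidth of the peak) and ranks candidate causal mutations.
#'
#' @param input Marker table (from [read_pooled_vcf()],
#'   [read_variants_table()] or the simulator), or a path to a `.vcf`/
#'   `.vcf.gz` or tab-separated file.
#' @param model A [theoretical_model()].
#' @param bandwidth_bp Smoothing bandwidth (default 2 Mb).
#' @param homozygosity_tolerance Passed to [rank_candidates()].
#' @param peak_statistic Track used for peak localization: smoothed
#'   mutant-pool SNP-index (`"mp"`, default, matching close-up inspection of
#'   the mutant pool) or inverted divergence (`"div"`).
#' @return An object of class `mapping_report`: a list with
#'   `candidate_chromosome`, `peak_position`, `candidate_interval`,
#'   `ranked_candidates`, `counts` (detected / scored / excluded /
#'   filtered), the scored `markers` table, the `closeup` track and the
#'   parameters used.
#' @export
run_pipeline <- function(input, model = theoretical_model(),
                         bandwidth_bp = 2e6, homozygosity_tolerance = 0,
                         peak_statistic = c("mp", "div")) {
  peak_statistic <- match.arg(peak_statistic)
  if (is.character(input) && length(input) == 1L) {
    input <- if (grepl("\\.vcf(\\.gz)?$", input)) {
      read_pooled_vcf(input)
    } else {
      read_variants_table(input)
    }
  }
  scored <- score_markers(input, model)
  filtered <- scored[passes_filter == TRUE]
  if (nrow(filtered) == 0L) {
    stop("mapping stage failed: no marker passes the divergence filter")
  }
  cand_chr <- select_candidate_chromosome(filtered)
  on_chr <- filtered[chrom == cand_chr][order(pos)]
  track_values <- if (peak_statistic == "mp") {
    on_chr$snp_index_mp
  } else {
    -on_chr$snp_index_div
  }
  sm <- smooth_track(on_chr$pos, track_values, bandwidth_bp)
  peak <- locate_peak(on_chr$pos, sm)
  near <- on_chr[abs(pos - peak) <= bandwidth_bp]
  interval <- c(start = min(near$pos), end = max(near$pos))
  candidates <- rank_candidates(on_chr, peak, homozygosity_tolerance)
  closeup <- data.table::data.table(
    pos = on_chr$pos, snp_index_mp = on_chr$snp_index_mp,
    smoothed = if (peak_statistic == "mp") sm else
      smooth_track(on_chr$pos, on_chr$snp_index_mp, bandwidth_bp))
  structure(list(
    candidate_chromosome = cand_chr,
    peak_position = peak,
    candidate_interval = interval,
    ranked_candidates = candidates,
    counts = list(n_detected = attr(scored, "n_input"),
                  n_scored = nrow(scored),
                  n_excluded = attr(scored, "n_excluded"),
                  n_filtered = nrow(filtered)),
    markers = scored,
    closeup = closeup,
    model = model,
    bandwidth_bp = bandwidth_bp,
    homozygosity_tolerance = homozygosity_tolerance,
    peak_statistic = peak_statistic), class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("<mapping_report>\n")
  cat(sprintf("  markers: %d detected, %d scored (%d excluded), %d filtered (DIV < %.4f)\n",
              x$counts$n_detected, x$counts$n_scored, x$counts$n_excluded,
              x$counts$n_filtered, x$model$div_threshold))
  cat(sprintf("  candidate chromosome: %s\n", x$candidate_chromosome))
  cat(sprintf("  peak: %s bp; interval: %s-%s bp\n",
              format(x$peak_position, big.mark = ","),
              format(x$candidate_interval[["start"]], big.mark = ","),
              format(x$candidate_interval[["end"]], big.mark = ",")))
  nc <- nrow(x$ranked_candidates)
  if (nc == 0L) {
    cat("  no candidate mutations\n")
  } else {
    cat(sprintf("  %d candidate mutation(s); top: %s:%d %s>%s %s (%s) %s|%s\n",
                nc, x$ranked_candidates$chrom[1L], x$ranked_candidates$pos[1L],
                x$ranked_candidates$ref[1L], x$ranked_candidates$alt[1L],
                x$ranked_candidates$effect[1L], x$ranked_candidates$impact[1L],
                x$ranked_candidates$hgvs_c[1L], x$ranked_candidates$hgvs_p[1L]))
  }
  invisible(x)
}
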