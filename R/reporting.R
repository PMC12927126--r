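## Assembling mapping outputs into the two standard visual summaries (the
## genome-wide divergence scatter with its 1/3 cutoff line, and the
## candidate-chromosome close-up of the mutant-pool SNP-index with smoothed
## curve and peak line) plus a machine-readable JSON run report.

#' Build plot-ready tracks from a mapping run
#'
#' @param markers Scored marker table ([score_markers()] output).
#' @param report A [run_pipeline()] `mapping_report`.
#' @return List of class `track_bundle`: `genome_wide` (chromosome,
#'   position, divergence, filter flag for every scored marker),
#'   `closeup` (position, mutant-pool SNP-index and smoothed value for
#'   filtered markers on the candidate chromosome), `threshold` (the
#'   divergence cutoff, 1/3 under the defaults) and `peak_position`.  When
#'   no marker passed the filter the close-up is empty and a warning is
#'   issued.
#' @export
build_tracks <- function(markers, report) {
  m <- data.table::as.data.table(markers)
  stopifnot(inherits(report, "mapping_report"))
  genome_wide <- m[, .(chrom, pos, snp_index_div, passes_filter)]
  closeup <- data.table::as.data.table(report$closeup)
  if (nrow(closeup) == 0L) {
    warning("no filtered markers: close-up track is empty")
  }
  structure(list(genome_wide = genome_wide,
                 closeup = closeup,
                 threshold = report$model$div_threshold,
                 peak_position = report$peak_position,
                 candidate_chromosome = report$candidate_chromosome),
            class = "track_bundle")
}

## open a bitmap device if the build supports one, else fall back to pdf;
## returns the actual file written
open_plot_device <- function(stem, width, height) {
  if (capabilities("png") || capabilities("cairo")) {
    file <- paste0(stem, ".png")
    grDevices::png(file, width = width, height = height, units = "in",
                   res = 150)
  } else {
    file <- paste0(stem, ".pdf")
    grDevices::pdf(file, width = width, height = height)
  }
  file
}

#' Render a mapping run to files
#'
#' Writes the genome-wide divergence scatter (dashed line at the filter
#' cutoff), the candidate-chromosome close-up (points, smoothed curve,
#' dashed vertical peak line), a JSON run report and the scored markers
#' TSV.
#'
#' @param tracks A [build_tracks()] bundle.
#' @param report The corresponding [run_pipeline()] report.
#' @param out_dir Output directory (created if needed).
#' @param plots Set `FALSE` to skip image generation (headless testing).
#' @return Named list of written file paths, invisibly.
#' @export
render_report <- function(tracks, report, out_dir, plots = TRUE) {
  stopifnot(inherits(tracks, "track_bundle"),
            inherits(report, "mapping_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(markers = file.path(out_dir, "markers.tsv"),
                report = file.path(out_dir, "report.json"))
  write_markers_tsv(report$markers, paths$markers)

  cand <- report$ranked_candidates
  report_json <- list(
    candidate_chromosome = report$candidate_chromosome,
    peak_position = report$peak_position,
    candidate_interval = as.list(report$candidate_interval),
    counts = report$counts,
    div_threshold = report$model$div_threshold,
    bandwidth_bp = report$bandwidth_bp,
    ranked_candidates = if (nrow(cand) == 0L) list() else
      lapply(seq_len(nrow(cand)), function(i) {
        as.list(cand[i, .(chrom, pos, ref, alt, snp_index_wp, snp_index_mp,
                          snp_index_div, effect, impact, gene_id, hgvs_c,
                          hgvs_p, distance_bp)])
      }))
  jsonlite::write_json(report_json, paths$report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (plots) {
    gw <- tracks$genome_wide
    gw$chrom <- factor(gw$chrom, levels = unique(gw$chrom))
    p1 <- ggplot2::ggplot(gw, ggplot2::aes(x = pos / 1e6, y = snp_index_div,
                                           colour = passes_filter)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.6) +
      ggplot2::geom_hline(yintercept = tracks$threshold, linetype = "dashed") +
      ggplot2::facet_grid(cols = ggplot2::vars(chrom), scales = "free_x",
                          space = "free_x") +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                              `TRUE` = "firebrick")) +
      ggplot2::labs(x = "position (Mb)", y = "SNP-index.DIV",
                    colour = "filtered") +
      ggplot2::theme_bw(base_size = 9) +
      ggplot2::theme(legend.position = "bottom",
                     panel.spacing = ggplot2::unit(0.1, "lines"))
    f1 <- open_plot_device(file.path(out_dir, "div_genome_wide"), 10, 3.5)
    print(p1); grDevices::dev.off()

    paths$genome_wide_plot <- f1
    if (nrow(tracks$closeup) > 0L) {
      cu <- tracks$closeup
      p2 <- ggplot2::ggplot(cu, ggplot2::aes(x = pos / 1e6)) +
        ggplot2::geom_point(ggplot2::aes(y = snp_index_mp),
                            colour = "grey40", size = 0.8) +
        ggplot2::geom_line(ggplot2::aes(y = smoothed), linewidth = 0.8) +
        ggplot2::geom_vline(xintercept = tracks$peak_position / 1e6,
                            linetype = "dashed") +
        ggplot2::labs(x = sprintf("%s position (Mb)",
                                  tracks$candidate_chromosome),
                      y = "SNP-index.MP") +
        ggplot2::theme_bw(base_size = 10)
      f2 <- open_plot_device(file.path(out_dir, "closeup_candidate_chromosome"),
                             6, 4)
      print(p2); grDevices::dev.off()
      paths$closeup_plot <- f2
    }
  }
  invisible(paths)
}
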