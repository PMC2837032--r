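#' Run the full two-library profiling pipeline
#'
#' Orchestrates the analysis stages in order — differential-expression
#' testing, library summary and reporting, GO-term enrichment between
#' the up- and downregulated sets, and guilt-by-association network
#' assembly — writing each stage's artifact under `out_dir`. Stages
#' whose inputs are missing (no annotations: enrichment, ranked tables
#' and network are skipped; no priors: network skipped) are skipped with
#' a notice. Output is deterministic given identical inputs and
#' thresholds.
#'
#' @param counts A [count_table()] or a path to a count TSV.
#' @param annotations Optional annotation data frame or TSV path.
#' @param priors Optional prior-edge data frame or TSV path.
#' @param out_dir Output directory (created if absent).
#' @param totals Optional full-library totals override `c(n_d, n_l)`.
#' @param alpha DE significance threshold (default 0.05).
#' @param fdr_threshold Enrichment reporting threshold (default 0.01).
#' @param top_n Rows per ranked table (default 20).
#' @param relfreq_threshold High-abundance cutoff (default 0.005).
#' @param edge_threshold Significant-interaction cutoff (default 0.9).
#' @return Invisibly, a list with the in-memory stage results (`de`,
#'   `summary`, `histogram`, `top_up`, `top_down`, `high_abundance`,
#'   `enrichment`, `network`) and `files`, the written artifact paths.
#' @export
run_pipeline <- function(counts, annotations = NULL, priors = NULL,
                         out_dir = ".", totals = NULL,
                         alpha = 0.05, fdr_threshold = 0.01, top_n = 20,
                         relfreq_threshold = 0.005, edge_threshold = 0.9) {
  if (is.character(counts)) counts <- read_count_table(counts, totals = totals)
  if (is.character(annotations)) annotations <- read_annotation_table(annotations)
  if (is.character(priors)) priors <- read_prior_edges(priors)
  stopifnot(inherits(counts, "count_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- path
    path
  }
  log_lines <- c(
    sprintf("dgepair %s", as.character(utils::packageVersion("dgepair"))),
    sprintf("alpha=%g fdr_threshold=%g top_n=%d relfreq_threshold=%g edge_threshold=%g",
            alpha, fdr_threshold, top_n, relfreq_threshold, edge_threshold),
    sprintf("totals n_d=%s n_l=%s%s", counts$totals[["n_d"]],
            counts$totals[["n_l"]],
            if (counts$totals_overridden) " (overridden)" else ""))

  message("[detest] testing ", nrow(counts$counts), " contigs")
  de <- compute_de_table(counts, alpha = alpha)
  put(format_de(de), "de.tsv")
  part <- de_partition(de, alpha)
  log_lines <- c(log_lines,
                 sprintf("significant=%d up=%d down=%d",
                         part[["significant"]], part[["up"]], part[["down"]]))

  message("[report] library summary, histogram, scatter")
  summ <- summarize_libraries(counts, de)
  put(as.data.frame(summ), "summary.tsv")
  hist <- hit_histogram(counts,
                        bin_uppers = default_bins(counts))
  put(hist, "histogram.tsv")
  scatter_export(de, file.path(out_dir, "scatter.tsv"))
  files[["scatter.tsv"]] <- file.path(out_dir, "scatter.tsv")
  ha <- high_abundance(de, relfreq_threshold)
  put(format_de(ha), "high_abundance.tsv")

  top_up <- top_down <- enr <- net <- NULL
  if (!is.null(annotations)) {
    top_up <- top_ranked(de, annotations, "up", n = top_n, alpha = alpha)
    top_down <- top_ranked(de, annotations, "down", n = top_n, alpha = alpha)
    put(top_up, "top_up.tsv"); put(top_down, "top_down.tsv")

    message("[enrich] GO overrepresentation, up vs down")
    up_ids <- de$contig_id[de$significant & de$direction == "up"]
    down_ids <- de$contig_id[de$significant & de$direction == "down"]
    enr <- go_enrichment(up_ids, down_ids, annotations, fdr_threshold)
    put(enr, "enrichment.tsv")

    if (!is.null(priors)) {
      message("[network] guilt-by-association assembly")
      net <- build_network(de, annotations, priors,
                           selection = "significant", alpha = alpha,
                           edge_threshold = edge_threshold)
      export_graph(net, file.path(out_dir, "network.sif"), "sif")
      export_graph(net, file.path(out_dir, "network.graphml"), "graphml")
      files[["network.sif"]] <- file.path(out_dir, "network.sif")
      files[["network.graphml"]] <- file.path(out_dir, "network.graphml")
      log_lines <- c(log_lines,
                     sprintf("network nodes=%d edges=%d significant_edges=%d",
                             nrow(net$nodes), nrow(net$edges),
                             sum(net$edges$significant)))
    } else message("[network] skipped: no prior-interaction table supplied")
  } else {
    message("[report/enrich/network] skipped: no annotation table supplied")
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  files[["run_log.txt"]] <- file.path(out_dir, "run_log.txt")
  invisible(list(de = de, partition = part, summary = summ, histogram = hist,
                 top_up = top_up, top_down = top_down, high_abundance = ha,
                 enrichment = enr, network = net, files = files))
}

# DE table with numeric columns rendered at full precision for TSV output
format_de <- function(de) {
  out <- as.data.frame(de)
  for (col in c("rel_d", "rel_l", "ratio", "p_value", "log10_p"))
    out[[col]] <- format(out[[col]], digits = 15, scientific = TRUE, trim = TRUE)
  out
}

# histogram bins wide enough for the observed maximum count
default_bins <- function(counts) {
  bins <- c(1, 5, 10, 50, 100, 500, 1000, Inf)
  bins
}

#' Write an annotation table
#'
#' Inverse of [read_annotation_table()]: GO terms are joined with `|`.
#'
#' @param annotations Annotation data frame with a `go_terms`
#'   list-column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  out <- data.frame(
    contig_id = annotations$contig_id,
    accession = annotations$accession,
    description = annotations$description,
    go_terms = vapply(annotations$go_terms, paste, character(1), collapse = "|"),
    ko_id = annotations$ko_id, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
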