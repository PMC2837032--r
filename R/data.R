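#' Library totals of the bundled Physarum sporulation survey
#'
#' Total read counts of the two cDNA libraries of the bundled example
#' study: 125,456 reads from competent plasmodia (library D) and 99,632
#' reads from plasmodia sampled six hours after far-red photoinduction
#' (library L). These are the full-library totals to use with any
#' subset of the study's contigs.
#'
#' @return Named numeric vector `c(n_d = 125456, n_l = 99632)`.
#' @export
physarum_library_totals <- function() {
  c(n_d = 125456, n_l = 99632)
}

#' Bundled example data: top-ranked Physarum transcripts
#'
#' The 20 most downregulated and 20 most upregulated annotated
#' transcripts (by relative-frequency ratio, among those with
#' significant differential expression) of a two-library *Physarum
#' polycephalum* light-induced sporulation survey, with their SwissProt
#' ortholog accessions and raw hit counts. The `group` column records
#' the published direction and `printed_order` the published rank
#' within each group. Counts in this subset must be tested against the
#' full library totals ([physarum_library_totals()]), not the subset
#' sums.
#'
#' @return Data frame with columns `contig_id`, `accession`,
#'   `description`, `hits_d`, `hits_l`, `group`, `printed_order`.
#' @examples
#' top40 <- physarum_top_table()
#' tot <- physarum_library_totals()
#' de <- ac_test(top40$hits_d, top40$hits_l, tot["n_d"], tot["n_l"],
#'               contig_id = top40$contig_id)
#' @export
physarum_top_table <- function() {
  path <- system.file("extdata", "physarum_top40.tsv", package = "dgepair")
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          colClasses = "character", quote = "")
  df$hits_d <- as.integer(df$hits_d)
  df$hits_l <- as.integer(df$hits_l)
  df$printed_order <- as.integer(df$printed_order)
  df
}

#' Bundled example data as pipeline inputs
#'
#' Repackages [physarum_top_table()] as a [count_table()] (with the
#' full-library totals override) plus a matching annotation data frame,
#' ready for [compute_de_table()], [top_ranked()] and friends.
#'
#' @return List with elements `counts` and `annotations`.
#' @export
physarum_top_inputs <- function() {
  df <- physarum_top_table()
  tot <- physarum_library_totals()
  ann <- data.frame(contig_id = df$contig_id, accession = df$accession,
                    description = df$description, ko_id = "",
                    stringsAsFactors = FALSE)
  ann$go_terms <- rep(list(character(0)), nrow(ann))
  list(counts = count_table(df[, c("contig_id", "hits_d", "hits_l")],
                            totals = tot),
       annotations = ann)
}
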