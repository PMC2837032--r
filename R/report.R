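#' Top-ranked differentially expressed transcripts
#'
#' Ranks significant transcripts of one direction by fold change
#' (majority/minority relative-frequency ratio, descending); ties are
#' broken by p-value ascending, then contig id ascending. By default
#' only annotated transcripts (non-empty ortholog accession) qualify,
#' matching the convention of reporting "top annotated" tables.
#'
#' @param de An `ac_de` table ([ac_test()] / [compute_de_table()]).
#' @param annotations Annotation data frame ([read_annotation_table()]);
#'   may be `NULL` when `annotated_only = FALSE`.
#' @param direction `"up"` or `"down"`.
#' @param n Maximum rows to return (default 20).
#' @param alpha Significance filter, strict `p < alpha` (default 0.05).
#' @param annotated_only Keep only contigs with a non-empty accession.
#' @return Data frame with columns `contig_id`, `accession`,
#'   `description`, `hits_d`, `hits_l`, `ratio`, `p_value`, in rank
#'   order. Fewer than `n` rows are returned (with a message) when fewer
#'   qualify.
#' @export
top_ranked <- function(de, annotations = NULL, direction = c("up", "down"),
                       n = 20, alpha = 0.05, annotated_only = TRUE) {
  direction <- match.arg(direction)
  stopifnot(n >= 1)
  de <- classify_de(de, alpha)
  rows <- de[de$significant & de$direction == direction, , drop = FALSE]
  if (annotated_only) {
    if (is.null(annotations))
      stop("annotations are required when annotated_only = TRUE")
    idx <- match(rows$contig_id, annotations$contig_id)
    acc <- ifelse(is.na(idx), "", annotations$accession[idx])
    desc <- ifelse(is.na(idx), "", annotations$description[idx])
    keep <- nzchar(acc)
    rows <- rows[keep, , drop = FALSE]
    rows$accession <- acc[keep]; rows$description <- desc[keep]
  } else {
    if (!is.null(annotations)) {
      idx <- match(rows$contig_id, annotations$contig_id)
      rows$accession <- ifelse(is.na(idx), "", annotations$accession[idx])
      rows$description <- ifelse(is.na(idx), "", annotations$description[idx])
    } else {
      rows$accession <- ""; rows$description <- ""
    }
  }
  ord <- order(-rows$ratio, rows$p_value, rows$contig_id)
  rows <- rows[ord, , drop = FALSE]
  if (nrow(rows) < n)
    message("only ", nrow(rows), " qualifying transcripts for direction '",
            direction, "' (requested ", n, ")")
  rows <- utils::head(rows, n)
  out <- rows[, c("contig_id", "accession", "description",
                  "hits_d", "hits_l", "ratio", "p_value")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' High-abundance transcripts
#'
#' Transcripts whose relative frequency exceeds a threshold in either
#' library (strict `>`), the selection rule behind labelling the most
#' abundant contigs on a relative-frequency scatter.
#'
#' @param de An `ac_de` table.
#' @param threshold Relative-frequency cutoff in (0,1); default 0.005.
#' @return The qualifying rows of `de`.
#' @export
high_abundance <- function(de, threshold = 0.005) {
  stopifnot(threshold > 0, threshold < 1)
  out <- de[de$rel_d > threshold | de$rel_l > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the relative-frequency scatter
#'
#' Writes a TSV with one row per contig (`contig_id`, `rel_d`, `rel_l`,
#' `direction`, `significant`), sufficient to re-plot the two-library
#' relative-frequency scatter; frequencies are written with 15
#' significant digits so a round-trip read reproduces them.
#'
#' @param de An `ac_de` table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
scatter_export <- function(de, path) {
  out <- data.frame(contig_id = de$contig_id,
                    rel_d = format(de$rel_d, digits = 15, scientific = TRUE,
                                   trim = TRUE),
                    rel_l = format(de$rel_l, digits = 15, scientific = TRUE,
                                   trim = TRUE),
                    direction = de$direction,
                    significant = de$significant,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Global differential-expression partition
#'
#' @param de An `ac_de` table.
#' @param alpha Significance threshold (strict `<`).
#' @return Named integer vector `c(significant, up, down)`;
#'   `significant == up + down` since ties have p = 1 and are never
#'   significant.
#' @export
de_partition <- function(de, alpha = 0.05) {
  de <- classify_de(de, alpha)
  up <- sum(de$significant & de$direction == "up")
  down <- sum(de$significant & de$direction == "down")
  c(significant = up + down, up = up, down = down)
}
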