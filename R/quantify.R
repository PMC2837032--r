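#' Differential-expression table for a whole count table
#'
#' Runs the Audic-Claverie test ([ac_test()]) on every contig of a count
#' table, using the table's library totals. Relative frequencies are
#' `hits / total` per library.
#'
#' @param table A [count_table()] object.
#' @param alpha Significance threshold (strict `<`), default 0.05.
#' @return An `ac_de` data frame, one row per contig, in table order.
#' @export
compute_de_table <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "count_table"))
  ac_test(table$counts$hits_d, table$counts$hits_l,
          n_d = table$totals[["n_d"]], n_l = table$totals[["n_l"]],
          contig_id = table$counts$contig_id, alpha = alpha)
}

#' Library-level detection and abundance summary
#'
#' Exhaustive counting over a count table: contigs detected per library
#' (>= 1 hit), represented with at least five hits, singletons (exactly
#' one hit), low-abundance contigs (<= 5 hits in both libraries), and
#' the strict relative-frequency comparison between libraries. If a DE
#' table is supplied, significant up/down counts are included.
#'
#' @param table A [count_table()] object.
#' @param de Optional `ac_de` table computed from `table`.
#' @return A list of class `library_summary`.
#' @export
summarize_libraries <- function(table, de = NULL) {
  stopifnot(inherits(table, "count_table"))
  d <- table$counts$hits_d; l <- table$counts$hits_l
  rel_d <- d / table$totals[["n_d"]]; rel_l <- l / table$totals[["n_l"]]
  out <- list(
    n_contigs      = length(d),
    detected_d     = sum(d >= 1),
    detected_l     = sum(l >= 1),
    at_least5_d    = sum(d >= 5),
    at_least5_l    = sum(l >= 5),
    at_least5_both = sum(d >= 5 & l >= 5),
    at_most5_both  = sum(d <= 5 & l <= 5),
    singletons_d   = sum(d == 1),
    singletons_l   = sum(l == 1),
    more_abundant_d = sum(rel_d > rel_l),
    more_abundant_l = sum(rel_l > rel_d),
    ties            = sum(rel_d == rel_l)
  )
  if (!is.null(de)) {
    stopifnot(nrow(de) == length(d))
    out$significant      <- sum(de$significant)
    out$significant_up   <- sum(de$significant & de$direction == "up")
    out$significant_down <- sum(de$significant & de$direction == "down")
  }
  class(out) <- "library_summary"
  out
}

#' @export
print.library_summary <- function(x, ...) {
  lab <- c(n_contigs = "Contigs with hit counts",
           detected_d = "Detected in library D (>= 1 hit)",
           detected_l = "Detected in library L (>= 1 hit)",
           at_least5_d = "At least 5 hits in D",
           at_least5_l = "At least 5 hits in L",
           at_least5_both = "At least 5 hits in both libraries",
           at_most5_both = "At most 5 hits in both libraries",
           singletons_d = "Single-hit contigs in D",
           singletons_l = "Single-hit contigs in L",
           more_abundant_d = "More abundant in D (relative frequency)",
           more_abundant_l = "More abundant in L (relative frequency)",
           ties = "Equal relative frequency",
           significant = "Significant differential expression",
           significant_up = "Upregulated, significant",
           significant_down = "Downregulated, significant")
  for (k in names(x))
    cat(sprintf("%-42s %s\n", lab[[k]], format(x[[k]], big.mark = ",")))
  invisible(x)
}

#' Convert a library summary to a two-column data frame
#'
#' @param x A `library_summary` object.
#' @param ... Unused.
#' @return Data frame with columns `statistic` and `value`.
#' @export
as.data.frame.library_summary <- function(x, ...) {
  data.frame(statistic = names(unclass(x)),
             value = unlist(unclass(x), use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Hit-count histogram with adjacent-upper-range bins
#'
#' Bins detected contigs (>= 1 hit; zero-count contigs are excluded from
#' that library's histogram) by hit count, where a count falls in the
#' first bin whose upper bound is greater than or equal to it: with the
#' default bins, a contig with 2 hits lands in the 2-5 range.
#'
#' @param table A [count_table()] object.
#' @param bin_uppers Strictly increasing integer upper bounds; the last
#'   may be `Inf`. Default `c(1, 5, 10, 50, 100, 500, 1000, Inf)`.
#' @return Data frame with columns `bin` (label), `upper`, `counts_d`,
#'   `counts_l`. Column sums equal the per-library detected counts.
#' @export
hit_histogram <- function(table, bin_uppers = c(1, 5, 10, 50, 100, 500, 1000, Inf)) {
  stopifnot(inherits(table, "count_table"),
            all(diff(bin_uppers) > 0), length(bin_uppers) >= 1)
  if (max(c(table$counts$hits_d, table$counts$hits_l, 0)) > max(bin_uppers))
    stop("largest count exceeds the last bin upper bound")
  lowers <- c(1, utils::head(bin_uppers, -1) + 1)
  lab <- ifelse(lowers == bin_uppers, as.character(lowers),
                paste0(lowers, "-", ifelse(is.finite(bin_uppers),
                                           bin_uppers, "")))
  bin_of <- function(v) {
    v <- v[v >= 1]
    tabulate(findInterval(v, lowers), nbins = length(bin_uppers))
  }
  data.frame(bin = lab, upper = bin_uppers,
             counts_d = bin_of(table$counts$hits_d),
             counts_l = bin_of(table$counts$hits_l),
             stringsAsFactors = FALSE)
}
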