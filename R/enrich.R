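#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Conditional (hypergeometric) exact test with the usual two-tailed
#' convention: the p-value sums the probabilities of all tables with the
#' observed margins whose point probability does not exceed that of the
#' observed table (with a 1e-7 relative slack on the comparison, the
#' convention of [stats::fisher.test()], which performs the computation).
#'
#' @param a Test-set members carrying the term.
#' @param b Test-set members without the term.
#' @param c_ Reference-set members carrying the term.
#' @param d Reference-set members without the term.
#' @return Two-tailed p-value in (0, 1]. Degenerate tables (an all-zero
#'   row or column) give 1.
#' @examples
#' fisher_two_tailed(3, 0, 0, 3)  # 0.1
#' @export
fisher_two_tailed <- function(a, b, c_, d) {
  cells <- c(a, b, c_, d)
  stopifnot(length(cells) == 4, all(cells >= 0), all(cells == floor(cells)))
  if (sum(cells) == 0) return(1)
  m <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  min(1, stats::fisher.test(m, alternative = "two.sided")$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: the adjusted value for the
#' i-th smallest p is `min_{j >= i} p_(j) * m / j`, capped at 1; output
#' order matches input order. Thin wrapper over
#' [stats::p.adjust()]`(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' GO-term overrepresentation between two contig sets
#'
#' For every GO term annotated on at least one participating contig,
#' builds the 2x2 table (test-set contigs with/without the term vs
#' reference-set contigs with/without) and applies the two-tailed Fisher
#' exact test, followed by Benjamini-Hochberg FDR adjustment across
#' terms. Only contigs carrying at least one GO term participate; each
#' contig counts once per term regardless of how often the term is
#' listed. Terms are tested exactly as annotated (no ontology-ancestor
#' propagation).
#'
#' @param test_ids Character vector of contig ids in the test set (e.g.
#'   the upregulated contigs).
#' @param ref_ids Character vector of contig ids in the reference set
#'   (e.g. the downregulated contigs); must be disjoint from `test_ids`.
#' @param annotations Annotation data frame as from
#'   [read_annotation_table()].
#' @param fdr_threshold Report terms with adjusted value strictly below
#'   this; default 0.01.
#' @return Data frame with one row per term: `term`, cells `a`, `b`,
#'   `c`, `d`, `p_value`, `fdr`, `overrepresented_in` ("test" when the
#'   term's frequency is higher in the test set, else "ref") and
#'   `reported` (`fdr < fdr_threshold`), sorted by `p_value`.
#' @export
go_enrichment <- function(test_ids, ref_ids, annotations,
                          fdr_threshold = 0.01) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  if (length(intersect(test_ids, ref_ids)))
    stop("test and reference contig sets must be disjoint")
  ann <- annotations[lengths(annotations$go_terms) > 0, , drop = FALSE]
  test_ann <- ann[ann$contig_id %in% test_ids, , drop = FALSE]
  ref_ann  <- ann[ann$contig_id %in% ref_ids,  , drop = FALSE]
  empty <- data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p_value = numeric(0),
                      fdr = numeric(0), overrepresented_in = character(0),
                      reported = logical(0), stringsAsFactors = FALSE)
  if (nrow(test_ann) == 0 && nrow(ref_ann) == 0) {
    warning("no GO-annotated contigs in either set")
    return(empty)
  }
  n_test <- nrow(test_ann); n_ref <- nrow(ref_ann)
  terms <- sort(unique(c(unlist(test_ann$go_terms), unlist(ref_ann$go_terms))))
  if (length(terms) == 0) return(empty)
  count_in <- function(set_terms) {
    tab <- table(factor(unique_per_contig(set_terms), levels = terms))
    as.integer(tab)
  }
  a <- count_in(test_ann$go_terms)
  cc <- count_in(ref_ann$go_terms)
  b <- n_test - a
  d <- n_ref - cc
  p <- mapply(fisher_two_tailed, a, b, cc, d)
  fdr <- bh_fdr(p)
  out <- data.frame(term = terms, a = a, b = b, c = cc, d = d,
                    p_value = p, fdr = fdr,
                    overrepresented_in =
                      ifelse(a / pmax(n_test, 1) > cc / pmax(n_ref, 1),
                             "test", "ref"),
                    reported = fdr < fdr_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}

# flatten a list of per-contig term vectors, one occurrence per contig
unique_per_contig <- function(term_list) {
  unlist(lapply(term_list, unique), use.names = FALSE)
}
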