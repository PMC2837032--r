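# Small programmatic fixtures shared across test files.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a 4-contig count table used by several quantitation tests
tiny_counts <- function() {
  count_table(data.frame(
    contig_id = c("c1", "c2", "c3", "c4"),
    hits_d = c(40L, 0L, 5L, 1L),
    hits_l = c(1L, 3L, 5L, 0L),
    stringsAsFactors = FALSE))
}

# deterministic annotation frame: `n` contigs named id_prefix1..n, each
# carrying the terms listed for its index in `term_map` (a list)
make_annotations <- function(ids, term_map) {
  ann <- data.frame(contig_id = ids,
                    accession = paste0("ACC_", ids),
                    description = "fixture", ko_id = "",
                    stringsAsFactors = FALSE)
  ann$go_terms <- term_map
  ann
}

# exhaustive-enumeration oracle for the two-tailed Fisher exact test
fisher_enum_oracle <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  lo <- max(0, k - m2); hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, m2, k)
  obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# naive direct-summation oracle for the AC lower tail, all y at once for
# one conditioning count x: shifted-exponent cumulative sum of the pmf
ac_tail_oracle <- function(y_max, x, n1, n2) {
  lt <- ac_pmf(0:y_max, x, n1, n2, log = TRUE)
  m <- max(lt)
  m + log(cumsum(exp(lt - m)))
}
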