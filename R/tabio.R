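#' Construct a two-library count table
#'
#' @param counts Data frame with columns `contig_id`, `hits_d`, `hits_l`.
#' @param totals Optional length-2 numeric `c(n_d, n_l)` overriding the
#'   column sums. Needed when a subset of contigs is analysed on its own:
#'   the test depends on the full library totals, not on the subset sums.
#' @return An object of class `count_table`: a list with elements
#'   `counts` (the validated data frame), `totals` (named `n_d`, `n_l`)
#'   and `totals_overridden`.
#' @export
count_table <- function(counts, totals = NULL) {
  need <- c("contig_id", "hits_d", "hits_l")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  counts <- counts[, need, drop = FALSE]
  counts$contig_id <- as.character(counts$contig_id)
  for (col in c("hits_d", "hits_l")) {
    v <- counts[[col]]
    if (any(is.na(v)) || any(v != floor(v)))
      stop("non-integer value in column '", col, "'")
    if (any(v < 0))
      stop("negative count in column '", col, "'")
    counts[[col]] <- as.integer(v)
  }
  dup <- counts$contig_id[duplicated(counts$contig_id)]
  if (length(dup))
    stop("duplicate contig_id: ", paste(unique(dup), collapse = ", "))
  sums <- c(n_d = sum(counts$hits_d), n_l = sum(counts$hits_l))
  overridden <- !is.null(totals)
  if (overridden) {
    stopifnot(length(totals) == 2, all(totals >= 1))
    if (totals[1] < sums["n_d"] || totals[2] < sums["n_l"])
      stop("override totals are smaller than the column sums")
    sums <- c(n_d = as.numeric(totals[1]), n_l = as.numeric(totals[2]))
  }
  structure(list(counts = counts, totals = sums,
                 totals_overridden = overridden),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d contigs; totals n_d = %s, n_l = %s%s\n",
              nrow(x$counts),
              format(x$totals[["n_d"]], big.mark = ","),
              format(x$totals[["n_l"]], big.mark = ","),
              if (x$totals_overridden) " (overridden)" else ""))
  invisible(x)
}

.read_tsv <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          quote = "", blank.lines.skip = TRUE)
  miss <- setdiff(columns, names(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a contig count table
#'
#' Reads a tab-separated table with header columns `contig_id`, `hits_d`
#' and `hits_l` (lines starting with `#` are skipped) and validates it:
#' counts must be non-negative integers and contig ids unique. Row order
#' is preserved.
#'
#' @param path Path to the TSV file.
#' @param totals Optional full-library totals override, see
#'   [count_table()].
#' @return A [count_table()] object.
#' @export
read_count_table <- function(path, totals = NULL) {
  df <- .read_tsv(path, c("contig_id", "hits_d", "hits_l"))
  for (col in c("hits_d", "hits_l")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != floor(v) | v < 0)
    if (length(bad))
      stop("invalid count in column '", col, "' at data line ", bad[1],
           " (contig '", df$contig_id[bad[1]], "')")
    df[[col]] <- as.integer(v)
  }
  count_table(df, totals = totals)
}

#' Write a contig count table
#'
#' @param x A [count_table()] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  utils::write.table(x$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a contig annotation table
#'
#' TSV with header columns `contig_id`, `accession`, `description`,
#' `go_terms` and (optionally) `ko_id`. GO terms are pipe-separated in
#' the one `go_terms` column and must match `GO:` followed by seven
#' digits. An empty `accession` marks an unannotated contig; contigs
#' absent from the file are treated as unannotated downstream.
#'
#' @param path Path to the TSV file.
#' @return Data frame with character columns and a list-column
#'   `go_terms` of character vectors.
#' @export
read_annotation_table <- function(path) {
  df <- .read_tsv(path, c("contig_id", "accession", "description", "go_terms"))
  if (is.null(df$ko_id)) df$ko_id <- ""
  dup <- df$contig_id[duplicated(df$contig_id)]
  if (length(dup))
    stop("duplicate contig_id in annotation table: ",
         paste(unique(dup), collapse = ", "))
  go <- strsplit(df$go_terms, "|", fixed = TRUE)
  go <- lapply(go, function(v) v[nzchar(v)])
  bad <- vapply(go, function(v) any(!grepl("^GO:\\d{7}$", v)), logical(1))
  if (any(bad))
    stop("malformed GO identifier for contig '",
         df$contig_id[which(bad)[1]], "' (expected GO:NNNNNNN)")
  out <- data.frame(contig_id = df$contig_id, accession = df$accession,
                    description = df$description, ko_id = df$ko_id,
                    stringsAsFactors = FALSE)
  out$go_terms <- go
  out
}

#' Read a prior-interaction edge table
#'
#' TSV with header columns `accession_a`, `accession_b`, `probability`
#' and (optionally) `provenance`. Edges are undirected: duplicate pairs
#' in either orientation are collapsed, keeping the maximum probability.
#' Self-edges and probabilities outside `[0, 1]` are rejected.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `accession_a`, `accession_b`,
#'   `probability`, `provenance`.
#' @export
read_prior_edges <- function(path) {
  df <- .read_tsv(path, c("accession_a", "accession_b", "probability"))
  if (is.null(df$provenance)) df$provenance <- ""
  p <- suppressWarnings(as.numeric(df$probability))
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad))
    stop("interaction probability outside [0,1] at data line ", bad[1])
  df$probability <- p
  self <- df$accession_a == df$accession_b
  if (any(self))
    stop("self-edge not allowed: ", df$accession_a[which(self)[1]])
  # canonical orientation, then keep max probability per pair
  a <- pmin(df$accession_a, df$accession_b)
  b <- pmax(df$accession_a, df$accession_b)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -df$probability)
  df <- df[ord, ]; a <- a[ord]; b <- b[ord]; key <- key[ord]
  keep <- !duplicated(key)
  out <- data.frame(accession_a = a[keep], accession_b = b[keep],
                    probability = df$probability[keep],
                    provenance = df$provenance[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read contig sequences from a FASTA file
#'
#' Sequence names are the first whitespace-delimited token of each
#' header line. Records with an empty sequence are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping contig id to sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  w <- Biostrings::width(seqs)
  if (any(w == 0))
    stop("empty sequence record: ", ids[which(w == 0)[1]])
  stats::setNames(as.character(seqs), ids)
}
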