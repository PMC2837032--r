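#' Guilt-by-association network from prior interactions
#'
#' Connects selected differentially expressed, annotated transcripts
#' using a supplied prior-interaction table: nodes are the selected
#' contigs with a non-empty ortholog accession, and an edge is drawn
#' whenever a prior edge links two selected contigs' accessions. Nodes
#' carry their expression direction (the up/down colouring of a
#' coexpression figure); edges may cross directions. An edge is flagged
#' significant when its interaction probability strictly exceeds
#' `edge_threshold`.
#'
#' @param de An `ac_de` table.
#' @param annotations Annotation data frame ([read_annotation_table()]).
#' @param priors Prior edge data frame ([read_prior_edges()]).
#' @param selection Node selection rule: `"significant"` (all contigs
#'   with `p < alpha`), `"top"` (the top `n` per direction via
#'   [top_ranked()]), or `"relfreq"` (relative frequency above
#'   `relfreq_threshold` in either library).
#' @param alpha,n,relfreq_threshold Parameters of the selection rules.
#' @param edge_threshold Strict probability cutoff for the significant
#'   flag; default 0.9.
#' @return An object of class `assoc_network`: list with data frames
#'   `nodes` (`contig_id`, `accession`, `direction`, `hits_d`, `hits_l`)
#'   and `edges` (`from`, `to` contig ids, `probability`,
#'   `significant`).
#' @export
build_network <- function(de, annotations, priors,
                          selection = c("significant", "top", "relfreq"),
                          alpha = 0.05, n = 20, relfreq_threshold = 0.005,
                          edge_threshold = 0.9) {
  selection <- match.arg(selection)
  sel <- switch(selection,
    significant = classify_de(de, alpha)$contig_id[classify_de(de, alpha)$significant],
    top = c(top_ranked(de, annotations, "up", n = n, alpha = alpha)$contig_id,
            top_ranked(de, annotations, "down", n = n, alpha = alpha)$contig_id),
    relfreq = high_abundance(de, relfreq_threshold)$contig_id)
  rows <- de[match(sel, de$contig_id), , drop = FALSE]
  idx <- match(rows$contig_id, annotations$contig_id)
  acc <- ifelse(is.na(idx), "", annotations$accession[idx])
  if (any(!nzchar(acc)))
    warning(sum(!nzchar(acc)), " selected contig(s) without an ortholog ",
            "accession were skipped")
  keep <- nzchar(acc)
  nodes <- data.frame(contig_id = rows$contig_id[keep],
                      accession = acc[keep],
                      direction = rows$direction[keep],
                      hits_d = rows$hits_d[keep], hits_l = rows$hits_l[keep],
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$accession))
    warning("an accession is shared by multiple selected contigs; ",
            "all contig pairings of its prior edges are expanded")
  edges <- data.frame(from = character(0), to = character(0),
                      probability = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(priors) && nrow(nodes)) {
    el <- list()
    for (i in seq_len(nrow(priors))) {
      ca <- nodes$contig_id[nodes$accession == priors$accession_a[i]]
      cb <- nodes$contig_id[nodes$accession == priors$accession_b[i]]
      if (length(ca) && length(cb)) {
        grid <- expand.grid(from = ca, to = cb, stringsAsFactors = FALSE)
        grid <- grid[grid$from != grid$to, , drop = FALSE]
        if (nrow(grid)) {
          grid$probability <- priors$probability[i]
          el[[length(el) + 1L]] <- grid
        }
      }
    }
    if (length(el)) {
      edges <- do.call(rbind, el)
      # undirected dedup, keep max probability
      a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
      key <- paste(a, b, sep = "\r")
      ord <- order(key, -edges$probability)
      edges <- edges[ord, ]; keep2 <- !duplicated(key[ord])
      edges <- edges[keep2, , drop = FALSE]
      edges$significant <- edges$probability > edge_threshold
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 edge_threshold = edge_threshold),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("assoc_network: %d nodes, %d interactions (%d with P > %g)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$significant),
              x$edge_threshold))
  invisible(x)
}

#' Convert an association network to an igraph object
#'
#' @param net An `assoc_network`.
#' @return An undirected [igraph::graph] with node attributes
#'   `accession`, `direction`, `hits_d`, `hits_l` and edge attributes
#'   `probability`, `significant`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export an association network to SIF or GraphML
#'
#' SIF writes one line per edge, `from interacts to` (an empty network
#' gives an empty file); GraphML (via igraph) carries all node and edge
#' attributes.
#'
#' @param net An `assoc_network`.
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(inherits(net, "assoc_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- if (nrow(net$edges))
      paste(net$edges$from, "interacts", net$edges$to) else character(0)
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}
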