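#!/usr/bin/env Rscript
# Stage 5: guilt-by-association network over the significant contigs of
# the simulated experiment. Prior interaction probabilities between
# ortholog accessions would normally come from curated interaction
# databases; here a SYNTHETIC prior table is drawn among the annotated
# significant contigs so the assembly and export machinery runs end to
# end (edges with probability > 0.9 are flagged significant).

library(dgepair)

counts <- read_count_table("results/sim/counts.tsv")
ann <- read_annotation_table("results/sim/annotations.tsv")
de <- suppressWarnings(compute_de_table(counts))
out <- "results/network"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# synthetic priors: random pairs among the accessions of significant,
# annotated contigs, mixed strong and weak probabilities
set.seed(5)
sig_ids <- de$contig_id[de$significant]
acc <- ann$accession[ann$contig_id %in% sig_ids & nzchar(ann$accession)]
pairs <- t(replicate(120, sample(acc, 2)))
priors <- data.frame(accession_a = pairs[, 1], accession_b = pairs[, 2],
                     probability = round(runif(120), 3),
                     provenance = "synthetic", stringsAsFactors = FALSE)
priors <- priors[priors$accession_a != priors$accession_b, ]
write.table(priors, file.path(out, "synthetic_priors.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

net <- suppressWarnings(build_network(de, ann, priors,
                                      selection = "significant",
                                      edge_threshold = 0.9))
export_graph(net, file.path(out, "network.sif"), "sif")
export_graph(net, file.path(out, "network.graphml"), "graphml")
cat(sprintf("Network: %d gene products, %d interactions (%d with P > 0.9)\n",
            nrow(net$nodes), nrow(net$edges), sum(net$edges$significant)))
cat(sprintf("Direction mix among nodes: %d up, %d down\n",
            sum(net$nodes$direction == "up"),
            sum(net$nodes$direction == "down")))
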