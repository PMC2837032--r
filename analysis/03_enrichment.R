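#!/usr/bin/env Rscript
# Stage 3: GO-term overrepresentation between the upregulated (test) and
# downregulated (reference) significant sets, two-tailed Fisher exact
# tests with Benjamini-Hochberg FDR < 0.01.

library(dgepair)

de <- read.delim("results/de/de.tsv")
ann <- read_annotation_table("results/sim/annotations.tsv")
out <- "results/enrich"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

up <- de$contig_id[de$significant & de$direction == "up"]
down <- de$contig_id[de$significant & de$direction == "down"]
enr <- go_enrichment(up, down, ann, fdr_threshold = 0.01)
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

rep <- enr[enr$reported, ]
cat(sprintf("%d GO terms tested; %d overrepresented at FDR < 0.01\n",
            nrow(enr), nrow(rep)))
if (nrow(rep)) {
  for (i in seq_len(nrow(rep)))
    cat(sprintf("  %s: %d/%d test vs %d/%d ref, p = %.3g, fdr = %.3g (%s)\n",
                rep$term[i], rep$a[i], rep$a[i] + rep$b[i], rep$c[i],
                rep$c[i] + rep$d[i], rep$p_value[i], rep$fdr[i],
                rep$overrepresented_in[i]))
}
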