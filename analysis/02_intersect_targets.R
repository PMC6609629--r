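#!/usr/bin/env Rscript
# Stage 2 — candidate panel by DEG-list intersection.
#
# Overlaps the binding-site-proximal DEG list with the knockdown DEG list
# (both simulated with the published list sizes), reports the Venn
# counts, and characterizes direction concordance on the overlap: in this
# design most shared genes flip direction between the two contrasts, the
# pattern expected when one contrast removes a transcriptional repressor.

suppressMessages(library(metasig))
dir.create("results", showWarnings = FALSE)

a <- read_deg_table("results/data/deg_list_a.tsv")
b <- read_deg_table("results/data/deg_list_b.tsv")
venn <- intersect_gene_lists(a, b)
conc <- direction_concordance(a, b)

jsonlite::write_json(
  c(venn[c("n_a", "n_b", "n_intersection", "n_a_only", "n_b_only")],
    list(discordant_fraction = conc$discordant_fraction,
         quadrants = as.list(conc$quadrants), genes = venn$genes)),
  "results/intersection.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("lists of %d and %d genes share %d (exclusive: %d / %d)\n",
            venn$n_a, venn$n_b, venn$n_intersection, venn$n_a_only,
            venn$n_b_only))
cat(sprintf("direction discordance on the overlap: %.2f\n",
            conc$discordant_fraction))
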