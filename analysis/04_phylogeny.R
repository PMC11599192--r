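#!/usr/bin/env Rscript
# Step 4 -- clustering support: pairwise similarity matrix of the ten
# exemplars (the widest single-species repertoire), a neighbor-joining tree
# on Poisson-corrected distances with 100 bootstrap replicates, and a
# clade-membership check of the co-ortholog exemplar against the cassette
# families.

suppressPackageStartupMessages(library(cd28family))
dir.create("results", showWarnings = FALSE)

recs <- read_fasta("results/exemplars_div0.fasta")
seqs <- stats::setNames(vapply(recs, `[[`, character(1), "sequence"),
                        sub("_sim_seed.*", "", vapply(recs, `[[`, character(1), "id")))

message("Pairwise percent-identity matrix (BLOSUM62, gaps -11/-1) ...")
m <- similarity_matrix(seqs)
print(round(m, 1))
utils::write.table(round(m, 2), "results/similarity_matrix.tsv",
                   sep = "\t", quote = FALSE)

message("Center-star MSA, NJ on Poisson-corrected distances, 100 bootstraps ...")
msa <- center_star_msa(seqs)
bs <- bootstrap_support(msa, n_reps = 100, seed = 202)
write_tree_newick(bs, "results/family_tree.nwk")
message("Tree written to results/family_tree.nwk")

co <- "cd28_ctla4_co_ortholog"
in_cassette <- clade_membership(bs$tree, co, c("cd28", "ctla4", "icos"))
message(sprintf("Co-ortholog exemplar clusters inside the CD28/CTLA4/ICOS clade: %s",
                in_cassette))
cd28h_clade <- clade_membership(bs$tree, "cd28h",
                                c("cd28hl1", "cd28hl2", "cd28hl3"))
message(sprintf("CD28H clusters with the CD28H-like paralogs: %s", cd28h_clade))
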