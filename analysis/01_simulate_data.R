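#!/usr/bin/env Rscript
# Step 1 -- build the synthetic inputs used throughout the analysis:
# one zero-divergence exemplar protein per family profile (plus a diverged
# set at 10% substitution with protected motifs), and gene-order tables for
# an ancestral genome and its 1x / 2x whole-genome-duplicated derivatives.

suppressPackageStartupMessages(library(cd28family))
dir.create("results", showWarnings = FALSE)
seed <- 101L

families <- c("CD28", "CTLA4", "ICOS", "CD28_CTLA4_CO_ORTHOLOG", "CD28H",
              "CD28HL1", "CD28HL2", "CD28HL3", "CD28X", "PD1")

message("Simulating one zero-divergence exemplar per profile ...")
exemplars <- lapply(seq_along(families), function(i)
  simulate_family_protein(families[i], divergence = 0, seed = seed + 7L * i))
names(exemplars) <- families
write_fasta(lapply(exemplars, `[[`, "record"), "results/exemplars_div0.fasta")

truth <- do.call(rbind, lapply(exemplars, function(e)
  cbind(family = e$truth$family, e$truth$motifs)))
utils::write.table(truth, "results/exemplars_div0_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

message("Simulating 20 diverged exemplars per profile (10% substitution) ...")
div <- list()
for (f in families) for (i in 1:20)
  div[[paste0(f, "_", i)]] <-
    simulate_family_protein(f, divergence = 0.10, protect_motifs = TRUE,
                            seed = seed + 100 * match(f, families) + i)$record
write_fasta(div, "results/exemplars_div10.fasta")

message("Simulating genomes: ancestral, and 1 / 2 rounds of WGD ...")
blocks <- ancestral_blocks()
for (d in 0:2) {
  g <- simulate_genome(blocks, wgd_events = d, loss_probability = 0,
                       seed = seed + d)
  for (nm in names(g$tables))
    write_gene_table(g$tables[[nm]], sprintf("results/genome_wgd%d_%s.tsv", d, nm))
}

message("Done. Exemplar FASTA, truth table and gene-order tables are under results/.")
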