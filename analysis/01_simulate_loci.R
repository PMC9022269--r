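#!/usr/bin/env Rscript

# Step 1: simulate a population of monomeric L1 loci with known truth.
#
# Uses the synthetic Tf-like promoter model shipped with the package
# (212-bp duplicated monomer, 197-bp M1, 205-bp tether), simulates 500
# loci with the default truncation model (start distribution peaked at
# the third monomer; single-nucleotide hotspots at offsets 83 and 86 on a
# uniform background), 1% substitutions, and 5% each of
# 3'-tether-truncated and decoy loci. Writes the locus FASTA and the
# truth table under results/simulation/.

suppressPackageStartupMessages(library(l1promoter))

seed <- 1L
outdir <- "results/simulation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

model <- read_promoter_model(
  system.file("extdata", "synthetic_tf_like_model.yaml", package = "l1promoter")
)
print(model)

cfg <- locus_sim_config(model, n = 500L)
sim <- simulate_loci(cfg, seed = seed)

write_fasta(sim$sequences, file.path(outdir, "loci.fa"))
write.table(sim$truth, file.path(outdir, "truth.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)

cat(sprintf(
  "simulated %d loci (%d clean, %d tether-truncated, %d decoy) with seed %d\n",
  nrow(sim$truth), sum(sim$truth$class == "clean"),
  sum(sim$truth$class == "tether_truncated"), sum(sim$truth$class == "decoy"),
  seed
))
cat(sprintf("wrote %s and %s\n", file.path(outdir, "loci.fa"), file.path(outdir, "truth.tsv")))
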