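#!/usr/bin/env Rscript

# Step 2: align the simulated loci to the 11-monomer extended query,
# filter, call 5' start bins, and tabulate the census; then score the
# calls against the simulation truth.
#
# Reads results/simulation/ from step 1 and writes the census reports
# under results/census/.

suppressPackageStartupMessages(library(l1promoter))

indir <- "results/simulation"
outdir <- "results/census"
stopifnot(file.exists(file.path(indir, "loci.fa")))

model <- read_promoter_model(
  system.file("extdata", "synthetic_tf_like_model.yaml", package = "l1promoter")
)
loci <- read_fasta(file.path(indir, "loci.fa"))
truth <- read.delim(file.path(indir, "truth.tsv"), stringsAsFactors = FALSE)

res <- run_locus_workflow(model, loci, outdir = outdir)
print(res$census)

clean <- truth[truth$class == "clean", ]
m <- merge(res$calls, clean, by = "locus_id", suffixes = c("", ".true"))
cat(sprintf(
  "bin recovery: %.1f%% (%d/%d clean loci)\n",
  100 * sum(m$bin == m$bin.true) / nrow(clean),
  sum(m$bin == m$bin.true), nrow(clean)
))
cat(sprintf(
  "offset recovery within +-1 nt: %.1f%%\n",
  100 * sum(m$bin == m$bin.true & abs(m$offset - m$offset.true) <= 1) / nrow(clean)
))
tether_ids <- truth$locus_id[truth$class == "tether_truncated"]
decoy_ids <- truth$locus_id[truth$class == "decoy"]
cat(sprintf(
  "rejected: %d/%d tether-truncated, %d/%d decoys\n",
  sum(!(tether_ids %in% res$calls$locus_id)), length(tether_ids),
  sum(!(decoy_ids %in% res$calls$locus_id)), length(decoy_ids)
))
cat(sprintf(
  "average monomer count (T and M11+ excluded): %.2f\n",
  res$census$avg_monomers
))
cat(sprintf("census reports written under %s\n", outdir))
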