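#!/usr/bin/env Rscript
# Whole-genome bits-per-base reproduction (FCM-M vs FCM-S).
#
# Computes, for each genome FASTA given on the command line, the multi-model
# (FCM-M: eight competing orders up to 16, 200-base blocks, side channel
# included) and single-best-model (FCM-S: best order per record) bpb under
# the default configuration. Reference figures for the bacterial genomes this
# pipeline targets: M. genitalium (NC_000908) FCM-M 1.812 / FCM-S 1.841,
# S. aureus MSSA476 (NC_002953) FCM-M 1.858, E. coli K-12 (NC_000913)
# FCM-M 1.901, each within about +/- 0.01 bpb.
#
# Genomes must be supplied locally (this environment has no network access),
# e.g. downloaded elsewhere with:
#   efetch -db nuccore -id NC_000908.2 -format fasta > NC000908.fa
#
# Usage: Rscript scripts/genome_bpb.R genome1.fa [genome2.fa ...]

suppressPackageStartupMessages(library(dnafcm))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0L) {
  cat("usage: Rscript scripts/genome_bpb.R <genome.fa> [...]\n")
  quit(status = 1L)
}

cfg <- competition_config()
cat(sprintf("%-30s %12s %10s %10s %6s\n",
            "file", "bases", "FCM-S", "FCM-M", "best_k"))
for (fa in args) {
  raws <- read_fasta(fa)
  recs <- mapply(filter_sequence, raws, names(raws), SIMPLIFY = FALSE)
  multi <- run_summary(lapply(recs, run_multi, cfg = cfg))
  singles <- lapply(recs, best_single, cfg = cfg)
  s_bits <- sum(vapply(singles, function(b) b$result$symbol_bits, numeric(1)))
  n <- multi$totals$modeled_bases
  cat(sprintf("%-30s %12d %10.4f %10.4f %6s\n",
              basename(fa), n, s_bits / n, multi$totals$bpb,
              paste(vapply(singles, `[[`, 0L, "depth"), collapse = ",")))
}
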