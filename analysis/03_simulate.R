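#!/usr/bin/env Rscript
# Generates the paper-shaped synthetic genome used by the downstream
# analyses: a 135,952 bp circle at 61.34% background A+T with 131 planted
# ORFs (plus promoter classes) and seven hr arrays of 99 bp imperfect
# palindromic repeats. The generator seed is fixed so 04/05 regenerate the
# identical genome.

suppressPackageStartupMessages(library(baculannot))
dir.create("results", showWarnings = FALSE)

params <- sim_params(seed = 1)
sim <- simulate_genome(params)
g <- sim$genome; tr <- sim$truth

cat("Simulated", g$length, "bp genome;", nrow(tr$orfs), "planted ORFs,",
    nrow(tr$hrs), "hr arrays with",
    paste(tr$hrs$copy_number, collapse = "/"), "repeat copies\n")
cat("Background A+T:", tr$background_at, "% over", tr$n_background,
    "non-feature bases (requested 61.34%)\n")
cat("Planted promoter classes:",
    paste(names(table(tr$orfs$promoter_class)),
          table(tr$orfs$promoter_class), collapse = ", "), "\n")

writeLines(c(paste0(">", g$name), g$sequence), "results/sim_genome.fasta")
write.table(tr$orfs, "results/sim_truth_orfs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tr$hr_units, "results/sim_truth_hr_units.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/sim_genome.fasta and truth tables\n")
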