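#!/usr/bin/env Rscript
# Simulate the full matched experiment: a 2000-gene transcriptome, planted
# regulatory modes for both post-stimulus time points (4 replicates x
# control/t0h/t2h), miRNA seed sites with per-site mRNA repression at 0 h,
# RPF/mRNA aligned reads, and tRNA-derived small RNA reads and counts.
# Everything downstream (02-06) starts from the plain-text files written
# here, so the whole analysis is reproducible from this one seed.

suppressPackageStartupMessages(library(ribopost))
seed <- 20200925L  # experiment master seed
out <- "results/simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_experiment(seed = seed)

write_transcriptome(sim$transcripts, file.path(out, "transcriptome.fasta"),
                    file.path(out, "regions.tsv"))
write_counts_tsv(sim$mrna, file.path(out, "counts_mrna.tsv"))
write_counts_tsv(sim$rpf, file.path(out, "counts_rpf.tsv"))
write_counts_tsv(sim$tsrna_counts, file.path(out, "counts_tsrna.tsv"))
write_reads_tsv(sim$rpf_reads, file.path(out, "reads_rpf.tsv"))
write_reads_tsv(sim$mrna_reads, file.path(out, "reads_mrna.tsv"))
write.table(sim$trna_refs, file.path(out, "trna_references.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$tsrna_reads, file.path(out, "tsrna_reads.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(mirna = names(sim$mirnas),
                       sequence = unname(sim$mirnas)),
            file.path(out, "mirnas.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(t(sim$site_counts), file.path(out, "mirna_site_counts.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write_truth_json(sim, file.path(out, "truth.json"))

cat(sprintf("simulated %d genes x %d samples per assay; %d RPF reads; %d tsRNA reads\n",
            nrow(sim$truth), ncol(sim$mrna$counts), nrow(sim$rpf_reads),
            nrow(sim$tsrna_reads)))
cat(sprintf("planted 0 h modes: %s\n",
            paste(names(table(sim$truth$mode_0h)),
                  table(sim$truth$mode_0h), collapse = ", ")))
cat("outputs under", out, "\n")
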