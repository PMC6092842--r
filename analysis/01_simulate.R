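#!/usr/bin/env Rscript

# Stage 1 -- build the synthetic study system.
#
# A 50-kb circular mitogenome-like molecule carrying the ten planted repeat
# pairs (lengths 72-3293 bp, identities 81.5-100, direct / inverted /
# palindromic), a companion plastid genome sharing two segments with it, and
# a 120x corrected-long-read pool drawn from a mixture of the master circle
# and two alternative conformations: an inversion across the largest
# inverted pair (R1, 8%) and the excision subcircles of a direct pair
# (R3, 1%).

suppressPackageStartupMessages(library(mtrecomb))

out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260928L

bp <- demo_blueprint(50000, seed = seed)
bp$plastid_shared_segments <- list(c(1200, 85), c(400, 100))
bp$plastid_length <- 25000L
built <- build_genome(bp)
message(sprintf("master genome: %s bp, %d planted pairs",
                format(built$genome$length, big.mark = ","),
                nrow(built$truth)))

mix <- c(master = 0.91, alt_R1 = 0.08, alt_R3 = 0.01)
confs <- list(master = list(genome = built$genome, weight = mix[["master"]]))
for (nm in c("alt_R1", "alt_R3")) {
  pid <- sub("alt_", "", nm)
  alts <- apply_recombination(built$genome, built$truth[built$truth$id == pid, ])
  lens <- vapply(alts, function(g) g$length, numeric(1))
  for (k in seq_along(alts))
    confs[[names(alts)[k]]] <- list(genome = alts[[k]],
                                    weight = mix[[nm]] * lens[k] / sum(lens))
}
sim <- simulate_reads(confs, read_sim_config(depth = 120, seed = seed + 1L))
message(sprintf("simulated %d reads, mean length %.0f bp",
                length(sim$reads), mean(nchar(sim$reads))))

write_fasta(built$genome$seq, file.path(out, "genome.fasta"))
write_fasta(built$plastid$seq, file.path(out, "plastid.fasta"))
write_fasta(sim$reads, file.path(out, "reads.fasta"))
write.table(built$truth, file.path(out, "planted_repeats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$provenance, file.path(out, "read_provenance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(built$plastid_truth, file.path(out, "planted_plastid_segments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", out)
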