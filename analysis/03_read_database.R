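#!/usr/bin/env Rscript

# Stage 3 -- build the mitochondrial read database.
#
# Recruits reads matching the mitogenome at e-value <= 1e-100, then purges
# reads whose plastid alignments cover > 85% of the read. The simulated pool
# is spiked with foreign (random) and pure-plastid reads so both filters
# have work to do.

suppressPackageStartupMessages(library(mtrecomb))

sim_dir <- "results/simulation"
out <- "results/readdb"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260930L

genome <- genome_sequence("master", read_fasta(file.path(sim_dir, "genome.fasta"))[[1]])
plastid <- genome_sequence("plastid", read_fasta(file.path(sim_dir, "plastid.fasta"))[[1]])
reads <- read_fasta(file.path(sim_dir, "reads.fasta"))

# spike-ins: 20 foreign reads and 20 pure plastid reads
set.seed(seed)
rand_read <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
foreign <- setNames(vapply(1:20, function(i) rand_read(5000), character(1)),
                    sprintf("foreign%02d", 1:20))
pl2 <- paste0(plastid$seq, plastid$seq)
plastid_reads <- setNames(vapply(1:20, function(i) {
  s <- sample.int(plastid$length, 1)
  substr(pl2, s, s + 4999)
}, character(1)), sprintf("plastid%02d", 1:20))
pool <- c(reads, foreign, plastid_reads)
message(sprintf("pool: %d reads (%d simulated + 40 spike-ins)",
                length(pool), length(reads)))

mt <- extract_mt_reads(pool, genome)
message(sprintf("after mitochondrial recruitment: %d reads", length(mt)))
purged <- remove_plastid_reads(mt, plastid)
message(sprintf("after plastid purge: %d reads (%d removed)",
                length(purged$reads), length(purged$removed)))

stats <- db_stats(purged$reads, genome$length)
message(sprintf("database: %d reads, mean %.0f bp, %.0fx depth",
                stats$n_reads, stats$mean_len, stats$depth))

write_fasta(purged$reads, file.path(out, "mt_reads.fasta"))
writeLines(purged$removed, file.path(out, "removed_read_ids.txt"))
jsonlite::write_json(stats, file.path(out, "db_stats.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", out)
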