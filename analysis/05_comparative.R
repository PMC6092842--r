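#!/usr/bin/env Rscript

# Stage 5 -- comparative utilities.
#
# Plastid-derived insert detection on the simulated organelle pair;
# conserved gene clusters and DCJ rearrangement distances on generated
# circular gene orders for three focal "early angiosperm" taxa plus two
# outgroups, with three planted ancestral clusters.

suppressPackageStartupMessages(library(mtrecomb))

sim_dir <- "results/simulation"
out <- "results/comparative"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20261002L

mito <- genome_sequence("mito", read_fasta(file.path(sim_dir, "genome.fasta"))[[1]])
plastid <- genome_sequence("plastid", read_fasta(file.path(sim_dir, "plastid.fasta"))[[1]])

ins <- find_plastid_inserts(mito, plastid)
message(sprintf("plastid-derived inserts: %d (longest %d bp at identity %.1f%%)",
                nrow(ins), ins$length[1], ins$identity_pct[1]))
write.table(ins, file.path(out, "plastid_inserts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

clusters <- list(c("rpl2", "rps19", "rps3", "rpl16"),
                 c("rps13", "rps11"),
                 c("rrn18", "rrn5"))
orders <- make_gene_orders(5, 40, planted_clusters = clusters,
                           shuffle_ops = c(20, 25, 30, 40, 40), seed = seed)
names(orders) <- c("nymphaea", "amborella", "liriodendron", "gymnosperm", "fern")
for (i in seq_along(orders)) orders[[i]]$taxon <- names(orders)[i]
write_gene_orders(orders, file.path(out, "gene_orders.txt"))

cl <- find_conserved_clusters(
  orders, focal = c("nymphaea", "amborella", "liriodendron"),
  outgroups = list(gymnosperms = "gymnosperm", ferns = "fern"))
message(sprintf("conserved clusters supported by an outgroup: %d", nrow(cl)))
print(cl)
write.table(cl, file.path(out, "conserved_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

dists <- data.frame(
  pair = c("nymphaea-amborella", "nymphaea-liriodendron"),
  dcj = c(dcj_distance(orders$nymphaea, orders$amborella),
          dcj_distance(orders$nymphaea, orders$liriodendron)))
print(dists)
write.table(dists, file.path(out, "dcj_distances.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", out)
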