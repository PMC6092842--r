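#!/usr/bin/env Rscript

# Stage 2 -- the repeat landscape of the master genome.
#
# Self-alignment at e-value 1e-6 / word 7, repeat pairs filtered at >= 30 bp
# and >= 80% identity; union repeat content; unique begin-end coordinate
# count; greedy incremental family clustering at 0.8; repeat content of
# intron-like feature intervals around the two largest planted pairs.

suppressPackageStartupMessages(library(mtrecomb))

sim_dir <- "results/simulation"
out <- "results/repeats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- genome_sequence("master", read_fasta(file.path(sim_dir, "genome.fasta"))[[1]])
pairs <- find_repeat_pairs(genome)
message(sprintf("found %d repeat pairs (%d unique copy coordinates)",
                nrow(pairs), count_unique_coordinates(pairs)))

uf <- repeat_union_fraction(genome, pairs)
message(sprintf("union repeat content: %s bp (%.1f%% of the genome)",
                format(uf$union_bp, big.mark = ","), 100 * uf$fraction))

fams <- cluster_families(repeat_copy_sequences(genome, pairs))
message(sprintf("%d repeat families from greedy incremental clustering",
                length(fams)))

# intron-like features: one fully inside the largest repeat copy, one
# partially overlapping, one overlapping other planted copies only marginally
big <- pairs[which.max(pairs$length), ]
feats <- data.frame(
  name = c("intron_inside_repeat", "intron_half_repeat", "intron_elsewhere"),
  start = c(big$a_start + 100, big$a_end - 1000, (big$b_end + 5000) %% genome$length),
  end = c(big$a_start + 2100, big$a_end + 1000, (big$b_end + 7000) %% genome$length))
frac <- interval_repeat_fraction(pairs, feats, genome$length)
print(frac)

write_pairs_tsv(pairs, file.path(out, "repeat_pairs.tsv"))
fam_tab <- do.call(rbind, lapply(seq_along(fams), function(i)
  data.frame(family = i, representative = fams[[i]]$representative,
             member = fams[[i]]$members,
             identity = round(fams[[i]]$member_identity, 3))))
write.table(fam_tab, file.path(out, "repeat_families.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_fasta(setNames(vapply(fams, `[[`, "", "rep_seq"),
                     paste0("family", seq_along(fams))),
            file.path(out, "family_representatives.fasta"))
write.table(frac, file.path(out, "feature_repeat_fractions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(n_pairs = nrow(pairs),
       n_unique_coordinates = count_unique_coordinates(pairs),
       union_bp = uf$union_bp, union_fraction = uf$fraction,
       n_families = length(fams)),
  file.path(out, "landscape.json"), auto_unbox = TRUE, digits = NA)
message("wrote ", out)
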