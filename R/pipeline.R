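#' Full analysis configuration with field-standard defaults
#'
#' Collects every threshold of the pipeline with its conventional default:
#' repeat self-search at e-value 1e-6, word 7, length >= 30 bp, identity >=
#' 80%; family clustering at similarity 0.8, word 5; read recruitment at
#' e-value 1e-100; plastid purge at read coverage > 0.85; read
#' classification at identity 99.5% with 200-bp flanks; validation flank
#' 2000 bp. The simulation block configures the synthetic genome (a
#' [demo_blueprint()] unless overridden) and read pool, and `mixture` gives
#' the master/alternative conformation weights.
#'
#' @param seed master seed for the run.
#' @param genome_length synthetic genome length.
#' @param depth simulated fold-coverage.
#' @param mixture named weights; `master` plus `alt_<pair>` entries.
#' @param repeat_search,clustering,read_extraction,plastid_purge,classification,validation
#'   stage threshold lists; any member may be overridden.
#' @return An object of class `analysis_config` (nested list).
#' @export
analysis_config <- function(seed = 1L,
                            genome_length = 100000L,
                            depth = 50,
                            mixture = c(master = 0.92, alt_R1 = 0.08),
                            repeat_search = list(),
                            clustering = list(),
                            read_extraction = list(),
                            plastid_purge = list(),
                            classification = list(),
                            validation = list()) {
  merge_block <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    depth = depth,
    mixture = mixture,
    repeat_search = merge_block(
      list(evalue = 1e-6, word = 7L, min_len = 30L, min_identity = 80),
      repeat_search),
    clustering = merge_block(list(threshold = 0.8, word = 5L), clustering),
    read_extraction = merge_block(list(evalue = 1e-100, word = 11L),
                                  read_extraction),
    plastid_purge = merge_block(list(coverage = 0.85), plastid_purge),
    classification = merge_block(
      list(identity = 99.5, flank = 200L, min_flank = 200L, word = 11L),
      classification),
    validation = merge_block(list(flank = 2000L), validation)),
    class = "analysis_config")
  validate_config(cfg)
  cfg
}

#' Validate an analysis configuration
#'
#' Checks every threshold against its documented domain before any compute.
#'
#' @param config an [analysis_config()] (or equivalent nested list).
#' @return `config`, invisibly; errors on the first violation.
#' @export
validate_config <- function(config) {
  chk <- function(cond, msg) if (!cond) stop("config: ", msg, call. = FALSE)
  chk(config$genome_length > 0, "genome_length must be positive")
  chk(config$depth > 0, "depth must be positive")
  chk(all(config$mixture >= 0) && sum(config$mixture) > 0,
      "mixture weights must be non-negative with positive sum")
  chk("master" %in% names(config$mixture), "mixture needs a 'master' entry")
  rs <- config$repeat_search
  chk(rs$evalue > 0, "repeat_search$evalue must be positive")
  chk(rs$word >= 4, "repeat_search$word must be >= 4")
  chk(rs$min_len >= 1, "repeat_search$min_len must be >= 1")
  chk(rs$min_identity >= 0 && rs$min_identity <= 100,
      "repeat_search$min_identity must be in [0, 100]")
  chk(config$clustering$threshold > 0 && config$clustering$threshold <= 1,
      "clustering$threshold must be in (0, 1]")
  chk(config$read_extraction$evalue > 0, "read_extraction$evalue must be positive")
  chk(config$plastid_purge$coverage >= 0 && config$plastid_purge$coverage <= 1,
      "plastid_purge$coverage must be in [0, 1]")
  cl <- config$classification
  chk(cl$identity >= 0 && cl$identity <= 100,
      "classification$identity must be in [0, 100]")
  chk(cl$flank > 0 && cl$min_flank > 0, "classification flanks must be positive")
  chk(config$validation$flank >= cl$flank,
      "validation$flank must be at least the classification flank")
  invisible(config)
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file.
#' @param config an [analysis_config()].
#' @return `read_config` returns the validated config; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mix <- unlist(raw$mixture)
  do.call(analysis_config, c(
    list(seed = raw$seed, genome_length = raw$genome_length,
         depth = raw$depth, mixture = mix),
    raw[intersect(names(raw), c("repeat_search", "clustering",
                                "read_extraction", "plastid_purge",
                                "classification", "validation"))]))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$mixture <- as.list(config$mixture)
  yaml::write_yaml(x, path)
  invisible(path)
}

# keep, for classification, only pairs not contained within a kept longer
# pair (both copies nested): overlapping partial sub-alignments of the same
# physical repeat add no information and multiply runtime
select_pairs_for_classification <- function(pairs, min_len = 50L) {
  pairs <- pairs[pairs$length >= min_len, , drop = FALSE]
  if (nrow(pairs) <= 1L) return(pairs)
  pairs <- pairs[order(-pairs$length), , drop = FALSE]
  contained <- function(s1, e1, s2, e2) s1 >= s2 - 10 & e1 <= e2 + 10
  keep <- rep(TRUE, nrow(pairs))
  for (i in seq_len(nrow(pairs))[-1]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (contained(pairs$a_start[i], pairs$a_end[i],
                    pairs$a_start[j], pairs$a_end[j]) &&
          contained(pairs$b_start[i], pairs$b_end[i],
                    pairs$b_start[j], pairs$b_end[j])) {
        keep[i] <- FALSE; break
      }
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Run the whole pipeline on a synthetic dataset
#'
#' Executes simulate -> find-repeats -> build-readdb -> detect-recombination
#' under one config and writes every stage's outputs plus a manifest to
#' `out_dir`. The synthetic master genome carries the config's planted
#' repeats; alternative conformations named in `mixture` are generated with
#' [apply_recombination()] (a direct pair's two subcircles share its weight
#' in proportion to their lengths).
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @param blueprint optional [genome_blueprint()]; defaults to
#'   [demo_blueprint()] at the config's genome length and seed.
#' @return Invisibly, a list with the main in-memory results: `genome`,
#'   `truth`, `pairs`, `landscape`, `db`, `recombination`, `manifest`.
#' @export
run_all <- function(config, out_dir, blueprint = NULL) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  set.seed(config$seed)
  if (is.null(blueprint))
    blueprint <- demo_blueprint(config$genome_length, seed = config$seed)

  # stage 1: simulate
  built <- build_genome(blueprint)
  genome <- built$genome
  truth <- built$truth
  conformations <- list(master = list(genome = genome,
                                      weight = config$mixture[["master"]]))
  for (nm in names(config$mixture)) {
    if (nm == "master") next
    pid <- sub("^alt_", "", nm)
    row <- truth[truth$id == pid, , drop = FALSE]
    if (nrow(row) == 0L)
      stop(sprintf("mixture names unknown pair '%s'", pid), call. = FALSE)
    alts <- apply_recombination(genome, row)
    lens <- vapply(alts, function(g) g$length, numeric(1))
    for (k in seq_along(alts))
      conformations[[names(alts)[k]]] <-
        list(genome = alts[[k]], weight = config$mixture[[nm]] * lens[k] / sum(lens))
  }
  sim_cfg <- read_sim_config(depth = config$depth, seed = config$seed + 1L)
  sim <- simulate_reads(conformations, sim_cfg)
  write_fasta(genome$seq, file.path(out_dir, "genome.fasta"))
  write_fasta(sim$reads, file.path(out_dir, "reads.fasta"))
  write.table(sim$provenance, file.path(out_dir, "read_provenance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth, file.path(out_dir, "planted_repeats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 2: repeat landscape
  rs <- config$repeat_search
  pairs <- find_repeat_pairs(genome, min_len = rs$min_len,
                             min_identity = rs$min_identity,
                             max_evalue = rs$evalue, word = rs$word)
  uf <- repeat_union_fraction(genome, pairs)
  n_coords <- count_unique_coordinates(pairs)
  fam_input <- repeat_copy_sequences(genome, head(pairs, 200L))
  families <- cluster_families(fam_input,
                               identity_threshold = config$clustering$threshold,
                               word = config$clustering$word)
  write_pairs_tsv(pairs, file.path(out_dir, "repeat_pairs.tsv"))
  landscape <- list(n_pairs = nrow(pairs), n_unique_coordinates = n_coords,
                    union_bp = uf$union_bp, union_fraction = uf$fraction,
                    n_families = length(families))
  jsonlite::write_json(landscape, file.path(out_dir, "repeat_landscape.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 3: read database
  mito_idx <- subject_index(genome, config$read_extraction$word)
  db_reads <- extract_mt_reads(sim$reads, mito_idx,
                               max_evalue = config$read_extraction$evalue,
                               word = config$read_extraction$word)
  stats <- db_stats(db_reads, genome$length)
  jsonlite::write_json(stats, file.path(out_dir, "readdb_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 4: recombination
  cl <- config$classification
  class_pairs <- select_pairs_for_classification(pairs)
  rec <- detect_recombination(genome, class_pairs, db_reads,
                              min_identity = cl$identity,
                              min_flank = cl$min_flank, flank = cl$flank,
                              validate_flank = config$validation$flank,
                              word = cl$word)
  write.table(rec$summary, file.path(out_dir, "recombination_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rec$verdicts, file.path(out_dir, "read_verdicts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rec_ids <- unlist(strsplit(rec$summary$recombined_read_ids, ",", fixed = TRUE))
  rec_ids <- rec_ids[nzchar(rec_ids)]
  if (length(rec_ids))
    write_fasta(sim$reads[unique(rec_ids)],
                file.path(out_dir, "recombined_reads.fasta"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mtrecomb")),
    seed = config$seed,
    config = unclass(config),
    counts = list(genome_length = genome$length,
                  n_reads_simulated = length(sim$reads),
                  n_reads_db = length(db_reads),
                  n_repeat_pairs = nrow(pairs),
                  n_pairs_classified = nrow(class_pairs),
                  n_recombined_reads = length(unique(rec_ids))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  manifest$config$mixture <- as.list(config$mixture)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(genome = genome, truth = truth, pairs = pairs,
                 landscape = landscape, db = stats, recombination = rec,
                 manifest = manifest))
}

#' Write a repeat-pair table in report coordinates
#'
#' 1-based inclusive positions; minus-strand copies printed with descending
#' coordinates, the convention of printed mitogenome repeat tables.
#'
#' @param pairs data.frame from [find_repeat_pairs()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  out <- data.frame(
    id = pairs$id, length = pairs$length,
    identity = sprintf("%.2f", pairs$identity_pct),
    direction = ifelse(pairs$palindromic, "palindromic", pairs$orientation),
    position_a = mapply(format_position, pairs$a_start, pairs$a_end,
                        pairs$a_strand),
    position_b = mapply(format_position, pairs$b_start, pairs$b_end,
                        pairs$b_strand),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Composition fractions of a mitogenome
#'
#' Report-style percentages of genome composition given component totals in
#' bp: each component as `100 * bp / genome_length`.
#'
#' @param genome_length genome length in bp.
#' @param components named numeric vector of component totals in bp (e.g.
#'   repeats, cis-spliced introns, intergenic spacers, protein exons).
#' @return data.frame with `component`, `bp`, `pct`.
#' @export
composition_fractions <- function(genome_length, components) {
  if (genome_length <= 0) stop("genome_length must be positive", call. = FALSE)
  data.frame(component = names(components), bp = as.numeric(components),
             pct = 100 * as.numeric(components) / genome_length,
             stringsAsFactors = FALSE)
}
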