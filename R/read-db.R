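#' Recruit mitochondrial reads by alignment to the mitogenome
#'
#' Keeps every read with at least one local alignment to the mitochondrial
#' reference at an e-value at or below the cut-off (default 1e-100, a
#' stringent threshold appropriate for multi-kilobase reads). Output order
#' follows input order; reads are never trimmed or split.
#'
#' @param reads named character vector of read sequences.
#' @param mito_ref mitochondrial reference, a [genome_sequence()].
#' @param max_evalue e-value cut-off (default 1e-100).
#' @param word seed word size for the read search (default 11).
#' @param scheme a [scoring_scheme()].
#' @return The retained subset of `reads` (named character vector).
#' @export
extract_mt_reads <- function(reads, mito_ref, max_evalue = 1e-100, word = 11L,
                             scheme = scoring_scheme()) {
  if (length(reads) == 0L) stop("reads must be non-empty", call. = FALSE)
  idx <- if (inherits(mito_ref, "subject_index")) mito_ref
  else subject_index(as_genome_sequence(mito_ref, "mito"), word)
  keep <- vapply(reads, function(r) {
    hits <- local_align_all(r, idx, min_word = word,
                            max_evalue = max_evalue, scheme = scheme)
    nrow(hits) > 0L
  }, logical(1))
  reads[keep]
}

# union fraction of the read covered by alignments to a reference
read_coverage_fraction <- function(read, ref, word, scheme, max_evalue,
                                   aggregate = c("union", "best")) {
  aggregate <- match.arg(aggregate)
  hits <- local_align_all(read, ref, min_word = word, max_evalue = max_evalue,
                          scheme = scheme)
  if (nrow(hits) == 0L) return(0)
  rl <- nchar(read)
  if (aggregate == "best") return((hits$q_end[1] - hits$q_start[1]) / rl)
  union_length(hits$q_start, hits$q_end, rl) / rl
}

#' Purge plastid-derived reads from a read set
#'
#' Removes reads whose alignments to the plastid reference cover strictly
#' more than `min_coverage` of the read length. Coverage aggregates the
#' union of read-side intervals over all plastid hits (a read matching the
#' plastid in two disjoint blocks is judged on their joint coverage);
#' single-best-hit coverage is available via `aggregate = "best"`. A
#' mitochondrial read carrying a plastid-derived insert is kept as long as
#' the insert covers no more than the threshold.
#'
#' @param mt_reads named character vector of reads.
#' @param plastid_ref plastid reference, a [genome_sequence()].
#' @param min_coverage removal threshold on covered read fraction,
#'   strict `>` (default 0.85).
#' @param aggregate `"union"` (default) or `"best"`.
#' @param max_evalue e-value cut-off for the plastid search.
#' @param word seed word size (default 11).
#' @param scheme a [scoring_scheme()].
#' @return list with `reads` (kept subset) and `removed` (character vector
#'   of removed read ids).
#' @export
remove_plastid_reads <- function(mt_reads, plastid_ref, min_coverage = 0.85,
                                 aggregate = c("union", "best"),
                                 max_evalue = 1e-6, word = 11L,
                                 scheme = scoring_scheme()) {
  aggregate <- match.arg(aggregate)
  if (is.null(plastid_ref)) stop("plastid reference required", call. = FALSE)
  if (!inherits(plastid_ref, "subject_index"))
    plastid_ref <- subject_index(as_genome_sequence(plastid_ref, "plastid"), word)
  cov <- vapply(mt_reads, read_coverage_fraction, numeric(1), ref = plastid_ref,
                word = word, scheme = scheme, max_evalue = max_evalue,
                aggregate = aggregate)
  drop <- cov > min_coverage
  list(reads = mt_reads[!drop], removed = names(mt_reads)[drop])
}

#' Read database statistics
#'
#' @param reads named character vector of reads.
#' @param genome_len reference genome length (for fold-depth).
#' @return list with `n_reads`, `mean_len`, `total_bp`, `depth`.
#' @export
db_stats <- function(reads, genome_len) {
  if (length(reads) == 0L) {
    warning("empty read set", call. = FALSE)
    return(list(n_reads = 0L, mean_len = 0, total_bp = 0, depth = 0))
  }
  total <- sum(nchar(reads))
  list(n_reads = length(reads), mean_len = total / length(reads),
       total_bp = total, depth = total / genome_len)
}
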