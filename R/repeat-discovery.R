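#' Enumerate repeat pairs by genome self-alignment
#'
#' Aligns a circular genome against itself on both strands, removes the
#' trivial full-length self hit, collapses each symmetric duplicate
#' (A vs B / B vs A) to one canonical pair, and applies length and identity
#' floors. Two copies whose intervals coincide on opposite strands are
#' flagged palindromic (self-inverted): a locus that aligns to its own
#' reverse complement.
#'
#' Overlapping hits are deliberately kept (no chaining or merging of nearby
#' pairs): imperfect, partially overlapping repeats are counted in an
#' overlapping fashion.
#'
#' @param genome a [genome_sequence()].
#' @param min_len minimum alignment length in bp (default 30).
#' @param min_identity minimum blast-style identity percent (default 80).
#' @param max_evalue self-search e-value cut-off (default 1e-6).
#' @param word seed word size (default 7).
#' @param scheme a [scoring_scheme()].
#' @return data.frame of canonical pairs: `id`, copy coordinates
#'   (`a_start`, `a_end`, `a_strand`, `b_start`, `b_end`, `b_strand`;
#'   0-based half-open, `a` lexicographically first), `length`,
#'   `identity_pct`, `orientation` (`direct`/`inverted`), `palindromic`,
#'   `score`, `evalue`. Sorted by length then identity, descending.
#' @export
find_repeat_pairs <- function(genome, min_len = 30L, min_identity = 80,
                              max_evalue = 1e-6, word = 7L,
                              scheme = scoring_scheme()) {
  genome <- as_genome_sequence(genome)
  aln <- local_align_all(genome, genome, min_word = word,
                         max_evalue = max_evalue, scheme = scheme, self = TRUE)
  aln <- aln[aln$length >= min_len & aln$identity_pct >= min_identity, ,
             drop = FALSE]
  if (nrow(aln) == 0L) return(empty_pair_df())

  a_start <- aln$q_start; a_end <- aln$q_end
  b_start <- aln$s_start; b_end <- aln$s_end
  b_strand <- aln$s_strand
  swap <- (b_start < a_start) | (b_start == a_start & b_end < a_end)
  tmp_s <- a_start[swap]; tmp_e <- a_end[swap]
  a_start[swap] <- b_start[swap]; a_end[swap] <- b_end[swap]
  b_start[swap] <- tmp_s; b_end[swap] <- tmp_e

  orientation <- ifelse(b_strand == "+", "direct", "inverted")
  ovl <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  span <- pmin(a_end - a_start, b_end - b_start)
  palindromic <- orientation == "inverted" & ovl >= 0.5 * span

  pairs <- data.frame(a_start = a_start, a_end = a_end, a_strand = "+",
                      b_start = b_start, b_end = b_end, b_strand = b_strand,
                      length = aln$length, identity_pct = aln$identity_pct,
                      orientation = orientation, palindromic = palindromic,
                      matches = aln$matches, score = aln$score,
                      evalue = aln$evalue, stringsAsFactors = FALSE)
  key <- paste(pairs$a_start, pairs$a_end, pairs$b_start, pairs$b_end,
               pairs$orientation)
  ord <- order(-pairs$score)
  pairs <- pairs[ord, , drop = FALSE]
  pairs <- pairs[!duplicated(key[ord]), , drop = FALSE]
  pairs <- pairs[order(-pairs$length, -pairs$identity_pct, pairs$a_start,
                       pairs$b_start), , drop = FALSE]
  pairs$id <- paste0("R", seq_len(nrow(pairs)))
  rownames(pairs) <- NULL
  pairs[, pair_columns()]
}

pair_columns <- function() {
  c("id", "a_start", "a_end", "a_strand", "b_start", "b_end", "b_strand",
    "length", "identity_pct", "orientation", "palindromic", "score", "evalue")
}

empty_pair_df <- function() {
  data.frame(id = character(), a_start = integer(), a_end = integer(),
             a_strand = character(), b_start = integer(), b_end = integer(),
             b_strand = character(), length = integer(),
             identity_pct = numeric(), orientation = character(),
             palindromic = logical(), score = integer(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Count repeated sequences by unique begin-end coordinates
#'
#' The number of distinct repeat-copy coordinates `(start, end, strand)`
#' across all hits of a self-search, counting both sides of every hit.
#' Repeated occurrences of the same coordinates count once.
#'
#' @param alignments data.frame from [local_align_all()] (self search,
#'   trivial hit removed), or a pair table from [find_repeat_pairs()].
#' @return Integer count of distinct copy coordinates.
#' @export
count_unique_coordinates <- function(alignments) {
  if (nrow(alignments) == 0L) return(0L)
  if (all(c("q_start", "s_start") %in% names(alignments))) {
    keys <- c(paste(alignments$q_start, alignments$q_end, "+"),
              paste(alignments$s_start, alignments$s_end, alignments$s_strand))
  } else {
    keys <- c(paste(alignments$a_start, alignments$a_end, alignments$a_strand),
              paste(alignments$b_start, alignments$b_end, alignments$b_strand))
  }
  length(unique(keys))
}

#' Union repeat content of a genome
#'
#' Union (not sum) of all repeat-copy intervals: overlapping and nested
#' copies count each position once, and the two strands of a palindromic
#' locus cover the same positions.
#'
#' @param genome a [genome_sequence()].
#' @param pairs data.frame from [find_repeat_pairs()].
#' @return list with `union_bp` and `fraction` (of genome length).
#' @export
repeat_union_fraction <- function(genome, pairs) {
  genome <- as_genome_sequence(genome)
  if (nrow(pairs) == 0L) return(list(union_bp = 0L, fraction = 0))
  starts <- c(pairs$a_start, pairs$b_start)
  ends <- c(pairs$a_end, pairs$b_end)
  ub <- union_length(starts, ends, genome$length)
  list(union_bp = ub, fraction = ub / genome$length)
}

#' Greedy incremental clustering of repeat sequences into families
#'
#' Sequences are sorted by length (descending, ties lexicographic) and each
#' one joins the first existing family whose representative it matches at or
#' above the identity threshold, else founds a new family; representatives
#' are therefore always the longest member. Identity is computed over the
#' aligned region of a local alignment (both strands searched) and the
#' alignment must cover at least 80% of the shorter sequence.
#'
#' @param repeat_sequences character vector of nucleotide sequences
#'   (optionally named).
#' @param identity_threshold fractional identity threshold (default 0.8).
#' @param word seed word size for the comparisons (default 5).
#' @param min_coverage required aligned fraction of the shorter sequence
#'   (default 0.8).
#' @param scheme a [scoring_scheme()].
#' @return list of families; each family is a list with `representative`
#'   (name), `rep_seq`, `members` (names) and `member_identity` (fraction
#'   identity of each member to the representative).
#' @export
cluster_families <- function(repeat_sequences, identity_threshold = 0.8,
                             word = 5L, min_coverage = 0.8,
                             scheme = scoring_scheme()) {
  n <- length(repeat_sequences)
  if (n == 0L) return(list())
  seqs <- toupper(repeat_sequences)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("rep", seq_len(n))
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]
  families <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]; nm <- names(seqs)[i]
    if (nchar(s) < word) {
      warning(sprintf("sequence '%s' shorter than word size; founding its own family", nm),
              call. = FALSE)
      families[[length(families) + 1L]] <-
        list(representative = nm, rep_seq = s, members = nm, member_identity = 1)
      next
    }
    placed <- FALSE
    for (f in seq_along(families)) {
      rep_seq <- families[[f]]$rep_seq
      if (nchar(rep_seq) < word) next
      hits <- local_align_all(s, genome_sequence("rep", rep_seq, circular = FALSE),
                              min_word = word, max_evalue = 10, scheme = scheme)
      if (nrow(hits) == 0L) next
      best <- hits[1L, ]
      shorter <- min(nchar(s), nchar(rep_seq))
      cov <- (best$q_end - best$q_start) / shorter
      idf <- best$identity_pct / 100
      if (idf >= identity_threshold && cov >= min_coverage) {
        families[[f]]$members <- c(families[[f]]$members, nm)
        families[[f]]$member_identity <- c(families[[f]]$member_identity, idf)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      families[[length(families) + 1L]] <-
        list(representative = nm, rep_seq = s, members = nm, member_identity = 1)
  }
  families
}

#' Repeat content of labelled feature intervals
#'
#' For each feature (e.g. an intron), the number of its positions covered by
#' at least one repeat copy, and the covered fraction. Large plant
#' mitochondrial introns can be dominated by repetitive elements; this
#' profiles that.
#'
#' @param pairs data.frame from [find_repeat_pairs()].
#' @param features data.frame with columns `name`, `start`, `end` (0-based
#'   half-open), or a path to a BED / GFF3 file (see [read_features()]).
#' @param genome_length circle length the coordinates live on.
#' @return data.frame with `name`, `length`, `covered_bp`, `fraction`.
#' @export
interval_repeat_fraction <- function(pairs, features, genome_length) {
  if (is.character(features) && length(features) == 1L)
    features <- read_features(features)
  req <- c("name", "start", "end")
  if (!all(req %in% names(features)))
    stop("features must have columns name, start, end", call. = FALSE)
  bad <- which(is.na(features$start) | is.na(features$end) |
                 features$end <= features$start |
                 features$start < 0 | features$end > genome_length)
  if (length(bad))
    stop(sprintf("malformed feature interval '%s'", features$name[bad[1L]]),
         call. = FALSE)
  # linearise repeat copies (split origin-wrapping copies in two)
  rs <- c(pairs$a_start, pairs$b_start) %% genome_length
  rl <- c(pairs$a_end - pairs$a_start, pairs$b_end - pairs$b_start)
  re <- rs + rl
  wrap <- re > genome_length
  starts <- c(rs[!wrap], rs[wrap], rep(0, sum(wrap)))
  ends <- c(re[!wrap], rep(genome_length, sum(wrap)), re[wrap] - genome_length)
  out <- features[, "name", drop = FALSE]
  out$length <- features$end - features$start
  out$covered_bp <- vapply(seq_len(nrow(features)), function(i) {
    fs <- features$start[i]; fe <- features$end[i]
    is <- pmax(starts, fs); ie <- pmin(ends, fe)
    keep <- ie > is
    if (!any(keep)) return(0L)
    union_length(is[keep], ie[keep], genome_length)
  }, integer(1))
  out$fraction <- out$covered_bp / out$length
  rownames(out) <- NULL
  out
}

#' Read feature intervals from BED or GFF3
#'
#' Dialect auto-detected from the file extension (`.bed` is 0-based
#' half-open; `.gff`/`.gff3` 1-based inclusive). Output coordinates are
#' normalised to 0-based half-open.
#'
#' @param path feature file.
#' @return data.frame with `name`, `start`, `end`.
#' @export
read_features <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("bed", "gff", "gff3"))
    stop("feature file must be .bed, .gff or .gff3", call. = FALSE)
  gr <- rtracklayer::import(path)
  nm <- NULL
  md <- as.data.frame(gr)
  for (cand in c("name", "Name", "ID", "gene_id"))
    if (cand %in% names(md) && !all(is.na(md[[cand]]))) { nm <- as.character(md[[cand]]); break }
  if (is.null(nm)) nm <- paste0("feature", seq_along(gr))
  data.frame(name = nm,
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

#' Extract the nucleotide sequences of all repeat copies
#'
#' @param genome a [genome_sequence()].
#' @param pairs data.frame from [find_repeat_pairs()].
#' @return Named character vector, two entries per pair (one for a
#'   palindromic pair), minus-strand copies reverse-complemented.
#' @export
repeat_copy_sequences <- function(genome, pairs) {
  genome <- as_genome_sequence(genome)
  out <- character(0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    a <- circular_substr(genome$seq, p$a_start, p$a_end)
    out[[paste0(p$id, "_a")]] <- a
    if (!p$palindromic) {
      b <- circular_substr(genome$seq, p$b_start, p$b_end)
      if (p$b_strand == "-") b <- revcomp(b)
      out[[paste0(p$id, "_b")]] <- b
    }
  }
  out
}
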