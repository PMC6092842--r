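#' @useDynLib mtrecomb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot rbinom rlnorm runif
#' @importFrom utils write.table head
NULL

VALID_BASES <- "ACGTN"

check_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(seq) == 0L)
    stop(what, " is empty", call. = FALSE)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop(sprintf("%s contains invalid character '%s' at position %d",
                 what, substr(seq, bad, bad), bad), call. = FALSE)
  invisible(seq)
}

#' A genome sequence with explicit topology
#'
#' Light container for a nucleotide sequence over `{A,C,G,T,N}` together with
#' a label and its topology. Plant mitochondrial genomes map as single
#' circular molecules, so all downstream coordinate arithmetic treats
#' positions modulo the length when `circular` is `TRUE`.
#'
#' @param id character label.
#' @param seq nucleotide string over `A`, `C`, `G`, `T`, `N` (uppercased).
#' @param circular logical; `TRUE` for circular topology.
#' @return An object of class `genome_sequence` (list with `id`, `seq`,
#'   `circular`, `length`).
#' @export
genome_sequence <- function(id, seq, circular = TRUE) {
  seq <- toupper(seq)
  check_sequence(seq, sprintf("sequence '%s'", id))
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular), length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

as_genome_sequence <- function(x, id = "genome", circular = TRUE) {
  if (inherits(x, "genome_sequence")) return(x)
  genome_sequence(id, as.character(x), circular)
}

#' Reverse complement of a nucleotide string
#'
#' Involution over the `{A,C,G,T,N}` alphabet; `N` complements to `N`.
#'
#' @param seq nucleotide string.
#' @return The reverse complement, same length.
#' @export
revcomp <- function(seq) {
  check_sequence(toupper(seq))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Alignment scoring scheme with Karlin-Altschul parameters
#'
#' Defaults mirror a blastn-like nucleotide preset: match +2, mismatch -3,
#' gap open 5, gap extend 2 (a gap of length k costs `gap_open +
#' k * gap_extend`). `lambda` is solved from
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` at uniform base composition when
#' not supplied; `K` defaults to the standard ungapped approximation 0.41.
#'
#' @param match positive match reward.
#' @param mismatch mismatch penalty (given as a positive number).
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @param lambda,K Karlin-Altschul parameters; `lambda = NULL` solves it
#'   numerically from the match/mismatch scores.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = 3L, gap_open = 5L,
                           gap_extend = 2L, lambda = NULL, K = 0.41) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("match reward must be positive", call. = FALSE)
  if (mismatch < 0L || gap_open < 0L || gap_extend < 0L)
    stop("penalties must be non-negative", call. = FALSE)
  if (0.25 * match - 0.75 * mismatch >= 0)
    stop("expected score per aligned pair must be negative", call. = FALSE)
  if (is.null(lambda)) {
    f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(-l * mismatch) - 1
    lambda <- uniroot(f, c(1e-6, 5), tol = 1e-12)$root
  }
  if (lambda <= 0 || K <= 0)
    stop("karlin parameters must be positive", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of chance
#' local alignments at or above `score` in a search space of `m * n`.
#'
#' @param score integer alignment score(s).
#' @param m,n effective query and subject lengths (positive).
#' @param scheme a [scoring_scheme()].
#' @return Numeric e-value(s), monotone decreasing in `score`.
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (any(m <= 0) || any(n <= 0))
    stop("sequence lengths must be positive", call. = FALSE)
  scheme$K * as.numeric(m) * as.numeric(n) * exp(-scheme$lambda * score)
}

# score at which the e-value drops to `max_evalue` (used to prune the engine)
min_score_for_evalue <- function(max_evalue, m, n, scheme) {
  s <- ceiling(log(scheme$K * as.numeric(m) * as.numeric(n) / max_evalue) /
                 scheme$lambda)
  max(as.integer(s), scheme$match * 4L)
}

#' Total covered length of intervals on a circular sequence
#'
#' Computes the number of distinct positions covered by a set of 0-based
#' half-open intervals on a circle of length `L`. Intervals may wrap the
#' origin (given either as `end > L` after modular normalisation of the
#' start, or with `start > end` meaning a wrap). Overlaps count once: this
#' is the union, not the sum.
#'
#' @param starts,ends integer vectors of 0-based interval starts and ends
#'   (half-open).
#' @param L circle length (positive).
#' @return Integer union length, at most `L`.
#' @export
union_length <- function(starts, ends, L) {
  if (length(L) != 1L || is.na(L) || L <= 0) stop("L must be positive", call. = FALSE)
  if (length(starts) != length(ends)) stop("starts/ends length mismatch", call. = FALSE)
  if (length(starts) == 0L) return(0L)
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  len <- ends - starts
  len[starts > ends] <- ends[starts > ends] - starts[starts > ends] + L
  if (any(len < 0)) stop("negative interval length", call. = FALSE)
  if (any(len >= L)) return(as.integer(L))
  s <- starts %% L
  e <- s + len
  # split wrapped intervals into two linear pieces
  wrap <- e > L
  ls <- c(s[!wrap], s[wrap], rep(0, sum(wrap)))
  le <- c(e[!wrap], rep(L, sum(wrap)), e[wrap] - L)
  keep <- le > ls
  ls <- ls[keep]; le <- le[keep]
  if (length(ls) == 0L) return(0L)
  o <- order(ls, le)
  ls <- ls[o]; le <- le[o]
  total <- 0; cs <- ls[1]; ce <- le[1]
  for (i in seq_along(ls)[-1]) {
    if (ls[i] <= ce) ce <- max(ce, le[i])
    else { total <- total + (ce - cs); cs <- ls[i]; ce <- le[i] }
  }
  as.integer(total + (ce - cs))
}

engine_defaults <- function() {
  list(xdrop = 25L, hsp_min = 28L, band_pad = 48L,
       max_chain_gap = 120L, max_occ = 512L)
}

#' All significant local alignments between two sequences
#'
#' Seed-and-extend local alignment on both strands: exact word seeds,
#' ungapped X-drop extension, colinear chaining, and banded affine-gap
#' Smith-Waterman over each chained region. A circular subject is searched
#' across its origin by doubling it (length `2L - 1`) and re-mapping hits
#' modulo `L`. Identity is `100 * matches / columns` with gap columns
#' counted, the common "blast identity".
#'
#' @param query,subject [genome_sequence()] objects or plain strings.
#' @param min_word exact seed word size (>= 4).
#' @param max_evalue e-value cut-off for reported alignments.
#' @param scheme a [scoring_scheme()].
#' @param self set `TRUE` when query and subject are the same molecule to
#'   suppress the trivial main-diagonal self alignment.
#' @return A data.frame, one row per alignment, ordered by score then
#'   coordinates, with 0-based half-open `q_start/q_end`, `s_start/s_end`,
#'   `s_strand` (`+`/`-`), `length` (columns incl. gaps), `matches`,
#'   `mismatches`, `gap_opens`, `identity_pct`, `score`, `evalue`.
#' @export
local_align_all <- function(query, subject, min_word = 7L, max_evalue = 1e-6,
                            scheme = scoring_scheme(), self = FALSE) {
  query <- as_genome_sequence(query, "query", circular = FALSE)
  if (min_word < 4L) stop("min_word must be >= 4", call. = FALSE)
  indexed <- inherits(subject, "subject_index")
  if (indexed) {
    if (subject$word != min_word)
      stop("subject index was built with a different word size", call. = FALSE)
    L <- subject$L
    doubled <- subject$doubled
    n_sub <- subject$n_sub
    sub_id <- subject$id
  } else {
    subject <- as_genome_sequence(subject, "subject")
    L <- subject$length
    sub_seq <- subject$seq
    doubled <- subject$circular && L > 1L
    if (doubled) sub_seq <- paste0(sub_seq, substr(subject$seq, 1L, L - 1L))
    n_sub <- nchar(sub_seq)
    sub_id <- subject$id
  }
  ed <- engine_defaults()
  min_rep <- min_score_for_evalue(max_evalue, query$length, L, scheme)
  hsp_min <- min(ed$hsp_min, min_rep)

  run <- function(strand, self_mod) {
    if (indexed) {
      ptr <- if (strand == "+") subject$fwd else subject$rev
      cpp_align_to_index(query$seq, ptr, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend, ed$xdrop,
                         as.integer(hsp_min), as.integer(min_rep), ed$band_pad,
                         ed$max_chain_gap, ed$max_occ, as.integer(self_mod))
    } else {
      subj <- if (strand == "+") sub_seq else revcomp(sub_seq)
      cpp_local_align(query$seq, subj, as.integer(min_word), scheme$match,
                      scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                      ed$xdrop, as.integer(hsp_min), as.integer(min_rep),
                      ed$band_pad, ed$max_chain_gap, ed$max_occ,
                      as.integer(self_mod))
    }
  }

  plus <- run("+", if (self) L else 0L)
  minus <- run("-", 0L)
  if (nrow(minus)) {
    ss <- n_sub - minus$s_end
    se <- n_sub - minus$s_start
    minus$s_start <- ss; minus$s_end <- se
  }
  plus$s_strand <- rep("+", nrow(plus))
  minus$s_strand <- rep("-", nrow(minus))
  hits <- rbind(plus, minus)
  if (nrow(hits) == 0L) return(empty_alignment_df())

  if (doubled) {
    # canonicalise to a start in [0, L); hits longer than L are artefacts of
    # the doubling (only the trivial self alignment can produce them)
    hits <- hits[hits$s_end - hits$s_start <= L, , drop = FALSE]
    shift <- (hits$s_start %/% L) * L
    shift[hits$s_start %% L == 0 & hits$s_start >= L] <- L
    hits$s_start <- hits$s_start - shift
    hits$s_end <- hits$s_end - shift
  }
  if (self) {
    triv <- hits$s_strand == "+" & hits$q_start == (hits$s_start %% L) &
      (hits$q_end - hits$q_start) == (hits$s_end - hits$s_start)
    hits <- hits[!triv, , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(empty_alignment_df())
  hits <- hits[!duplicated(hits[, c("q_start", "q_end", "s_start", "s_end",
                                    "s_strand")]), , drop = FALSE]
  hits$identity_pct <- 100 * hits$matches / hits$columns
  hits$evalue <- evalue(hits$score, query$length, L, scheme)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  hits$length <- hits$columns
  hits$query <- query$id
  hits$subject <- sub_id
  hits <- hits[order(-hits$score, hits$q_start, hits$s_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, alignment_columns()]
}

#' Prebuilt word index over a subject genome
#'
#' Builds the seed word index for both strands once so that many queries
#' (e.g. thousands of reads) can be aligned against the same subject without
#' re-hashing it. Circular subjects are doubled, as in [local_align_all()].
#'
#' @param subject a [genome_sequence()] or plain string.
#' @param word seed word size (must match the later `min_word`).
#' @return An object of class `subject_index`, acceptable as the `subject`
#'   argument of [local_align_all()].
#' @export
subject_index <- function(subject, word = 11L) {
  subject <- as_genome_sequence(subject, "subject")
  L <- subject$length
  sub_seq <- subject$seq
  doubled <- subject$circular && L > 1L
  if (doubled) sub_seq <- paste0(sub_seq, substr(subject$seq, 1L, L - 1L))
  structure(list(id = subject$id, L = L, doubled = doubled,
                 n_sub = nchar(sub_seq), word = as.integer(word),
                 fwd = cpp_index_build(sub_seq, as.integer(word)),
                 rev = cpp_index_build(revcomp(sub_seq), as.integer(word))),
            class = "subject_index")
}

alignment_columns <- function() {
  c("query", "subject", "q_start", "q_end", "s_start", "s_end", "s_strand",
    "length", "matches", "mismatches", "gap_opens", "identity_pct", "score",
    "evalue")
}

empty_alignment_df <- function() {
  df <- data.frame(query = character(), subject = character(),
                   q_start = integer(), q_end = integer(),
                   s_start = integer(), s_end = integer(),
                   s_strand = character(), length = integer(),
                   matches = integer(), mismatches = integer(),
                   gap_opens = integer(), identity_pct = numeric(),
                   score = integer(), evalue = numeric(),
                   stringsAsFactors = FALSE)
  df
}

#' Write alignments in 12-column tabular format
#'
#' Standard tab-separated hit table (query, subject, identity, alignment
#' length, mismatches, gap opens, then 1-based inclusive query and subject
#' coordinates, e-value, score). Minus-strand subject coordinates are written
#' descending, as conventional for nucleotide hit tables.
#'
#' @param alignments data.frame from [local_align_all()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alignments, path) {
  a <- alignments
  qs <- a$q_start + 1L; qe <- a$q_end
  ss <- ifelse(a$s_strand == "+", a$s_start + 1L, a$s_end)
  se <- ifelse(a$s_strand == "+", a$s_end, a$s_start + 1L)
  out <- data.frame(query = a$query, subject = a$subject,
                    identity = sprintf("%.2f", a$identity_pct),
                    length = a$length, mismatches = a$mismatches,
                    gap_opens = a$gap_opens, q_start = qs, q_end = qe,
                    s_start = ss, s_end = se,
                    evalue = format(a$evalue, digits = 3),
                    score = a$score, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a (multi-)FASTA file
#'
#' @param path FASTA file.
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# circular substring extraction, 0-based half-open, end may exceed L
circular_substr <- function(seq, start, end) {
  L <- nchar(seq)
  start <- start %% L
  len <- end - start
  if (len <= 0) stop("empty circular substring", call. = FALSE)
  if (start + len <= L) return(substr(seq, start + 1L, start + len))
  paste0(substr(seq, start + 1L, L), circular_substr(seq, 0L, len - (L - start)))
}
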