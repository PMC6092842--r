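#' Alternative genome conformations produced by recombination across a repeat pair
#'
#' Homologous recombination between the two copies of a repeat rearranges a
#' circular genome in an orientation-dependent way:
#' \itemize{
#'   \item inverted pair: one circular conformation with the segment from the
#'     start of copy A to the end of copy B reverse-complemented in place
#'     (the region between the copies, and one repeat copy at each junction,
#'     is inverted);
#'   \item direct pair: excision splits the master circle into two subgenomic
#'     circles, one per repeat copy, whose lengths sum to the master length;
#'   \item palindromic (self-inverted) locus: one conformation with the locus
#'     replaced in place by its reverse complement.
#' }
#' Base content is conserved up to strand convention (an inverted segment
#' carries the complementary bases; A+T and C+G totals are invariant, and
#' for direct pairs the two subcircles partition the master exactly).
#'
#' @param genome a circular [genome_sequence()].
#' @param pair one-row data.frame in [find_repeat_pairs()] layout.
#' @return A named list of [genome_sequence()] conformations (two entries
#'   for a direct pair, one otherwise).
#' @export
apply_recombination <- function(genome, pair) {
  genome <- as_genome_sequence(genome)
  p <- as.list(pair[1, ])
  L <- genome$length
  if (p$a_end > L || p$b_end > L || p$a_start < 0 || p$b_start < 0)
    stop("pair coordinates outside the genome", call. = FALSE)
  overlap <- min(p$a_end, p$b_end) - max(p$a_start, p$b_start)
  if (!isTRUE(p$palindromic) && overlap > 0)
    stop("unsupported geometry: overlapping non-palindromic repeat copies",
         call. = FALSE)
  if (isTRUE(p$palindromic)) {
    s <- p$a_start; e <- max(p$a_end, p$b_end)
    alt <- paste0(substr(genome$seq, 1L, s),
                  revcomp(substr(genome$seq, s + 1L, e)),
                  substr(genome$seq, e + 1L, L))
    out <- list(genome_sequence(paste0("alt_", p$id), alt, circular = TRUE))
    names(out) <- paste0("alt_", p$id)
    return(out)
  }
  if (p$orientation == "inverted") {
    s <- p$a_start; e <- p$b_end
    alt <- paste0(substr(genome$seq, 1L, s),
                  revcomp(substr(genome$seq, s + 1L, e)),
                  substr(genome$seq, e + 1L, L))
    out <- list(genome_sequence(paste0("alt_", p$id), alt, circular = TRUE))
    names(out) <- paste0("alt_", p$id)
    return(out)
  }
  # direct pair: two subgenomic circles [a_start, b_start) and [b_start, a_start)
  c1 <- circular_substr(genome$seq, p$a_start, p$b_start)
  c2 <- circular_substr(genome$seq, p$b_start, p$a_start + L)
  out <- list(genome_sequence(paste0("alt_", p$id, "_sub1"), c1, circular = TRUE),
              genome_sequence(paste0("alt_", p$id, "_sub2"), c2, circular = TRUE))
  names(out) <- vapply(out, function(g) g$id, character(1))
  out
}

flank_before <- function(genome, pos, flank) {
  if (!genome$circular && pos - flank < 0)
    stop("flank overruns the start of a linear sequence", call. = FALSE)
  circular_substr(genome$seq, (pos - flank) %% genome$length, (pos - flank) %% genome$length + flank)
}

flank_after <- function(genome, pos, flank) {
  if (!genome$circular && pos + flank > genome$length)
    stop("flank overruns the end of a linear sequence", call. = FALSE)
  circular_substr(genome$seq, pos %% genome$length, pos %% genome$length + flank)
}

#' Master and recombinant reference sequences for one repeat pair
#'
#' Builds the reference set used to classify reads: the two master templates
#' (each repeat copy with `flank` bp of upstream and downstream master
#' sequence) and the recombinant references (each recombination junction
#' with the flanks it would acquire after recombination across the pair).
#' Because the crossover point inside an imperfect repeat is unobservable,
#' each of the two junction structures is emitted in both repeat-sequence
#' variants (copy A's and copy B's sequence) when identity < 100, giving 4
#' recombinant references; identical copies collapse the variants, giving 2.
#' A palindromic locus yields one template and one recombinant (the in-place
#' reverse complement), distinguishable precisely because its identity is
#' below 100.
#'
#' @param genome a circular [genome_sequence()].
#' @param pair one-row data.frame in [find_repeat_pairs()] layout.
#' @param flank flank length in bp (200 at screening, 2000 at validation).
#' @return An object of class `reference_set`: list with `pair_id`, `flank`,
#'   `pair`, and `refs` (data.frame: `name`, `role` = template/recombinant,
#'   `seq`, `up_len`, `core_len`, `down_len`).
#' @export
build_reference_set <- function(genome, pair, flank = 200L) {
  genome <- as_genome_sequence(genome)
  p <- as.list(pair[1, ])
  flank <- as.integer(flank)
  span <- max(p$a_end, p$b_end) - min(p$a_start, p$b_start)
  if (genome$length <= 2L * flank + span)
    stop("genome too short for the requested flank", call. = FALSE)
  perfect <- p$identity_pct >= 100

  add <- function(df, name, role, up, core, down) {
    rbind(df, data.frame(name = name, role = role,
                         seq = paste0(up, core, down),
                         up_len = nchar(up), core_len = nchar(core),
                         down_len = nchar(down), stringsAsFactors = FALSE))
  }
  refs <- data.frame(name = character(), role = character(), seq = character(),
                     up_len = integer(), core_len = integer(),
                     down_len = integer(), stringsAsFactors = FALSE)

  if (isTRUE(p$palindromic)) {
    s <- p$a_start; e <- max(p$a_end, p$b_end)
    S <- circular_substr(genome$seq, s, e)
    U <- flank_before(genome, s, flank)
    D <- flank_after(genome, e, flank)
    refs <- add(refs, "template", "template", U, S, D)
    refs <- add(refs, "alt", "recombinant", U, revcomp(S), D)
  } else {
    RA <- circular_substr(genome$seq, p$a_start, p$a_end)
    RBraw <- circular_substr(genome$seq, p$b_start, p$b_end)
    U1 <- flank_before(genome, p$a_start, flank)
    D1 <- flank_after(genome, p$a_end, flank)
    U2 <- flank_before(genome, p$b_start, flank)
    D2 <- flank_after(genome, p$b_end, flank)
    refs <- add(refs, "template_a", "template", U1, RA, D1)
    refs <- add(refs, "template_b", "template", U2, RBraw, D2)
    if (p$orientation == "direct") {
      # subcircle junctions: (U2, x, D1) and (U1, x, D2)
      refs <- add(refs, "alt1_a", "recombinant", U2, RA, D1)
      refs <- add(refs, "alt2_b", "recombinant", U1, RBraw, D2)
      if (!perfect) {
        refs <- add(refs, "alt1_b", "recombinant", U2, RBraw, D1)
        refs <- add(refs, "alt2_a", "recombinant", U1, RA, D2)
      }
    } else {
      # inversion junctions: (U1, x, rc(U2)) and (rc(D1), x, D2)
      refs <- add(refs, "alt1_a", "recombinant", U1, revcomp(RBraw), revcomp(U2))
      refs <- add(refs, "alt2_b", "recombinant", revcomp(D1), revcomp(RA), D2)
      if (!perfect) {
        refs <- add(refs, "alt1_b", "recombinant", U1, RA, revcomp(U2))
        refs <- add(refs, "alt2_a", "recombinant", revcomp(D1), RBraw, D2)
      }
    }
  }
  rownames(refs) <- NULL
  structure(list(pair_id = p$id, flank = flank, pair = pair[1, ], refs = refs),
            class = "reference_set")
}

# best hits of every reference of one or more reference sets against a read;
# returns the raw per-(ref,strand) matrix plus the ref bookkeeping table
map_read_to_refs <- function(read, refs, word, scheme, min_report) {
  ed <- engine_defaults()
  cpp_map_refs_to_read(refs$seq, read, revcomp(read), as.integer(word),
                       scheme$match, scheme$mismatch, scheme$gap_open,
                       scheme$gap_extend, ed$xdrop,
                       as.integer(min(ed$hsp_min, min_report)),
                       as.integer(min_report), ed$band_pad, ed$max_chain_gap,
                       ed$max_occ)
}

classification_min_report <- function(min_flank) max(24L, as.integer(min_flank))

# qualification and verdict for one read against one refset's rows of the
# hit matrix; `containment` additionally requires the alignment to cover the
# read's full overlap with the reference (stage-2 semantics)
judge_read <- function(hits, refs, read_len, min_identity, min_flank,
                       containment = FALSE, slack = 30L) {
  score <- hits[, "score"]
  ok <- score > 0
  if (any(ok)) {
    idx <- which(ok)
    ident <- 100 * hits[idx, "matches"] / pmax(hits[idx, "columns"], 1)
    up_len <- refs$up_len[hits[idx, "ref"]]
    core_len <- refs$core_len[hits[idx, "ref"]]
    ref_len <- up_len + core_len + refs$down_len[hits[idx, "ref"]]
    cov_up <- pmax(0, up_len - hits[idx, "q_start"])
    cov_dn <- pmax(0, hits[idx, "q_end"] - (up_len + core_len))
    qual <- ident >= min_identity & cov_up >= min_flank & cov_dn >= min_flank
    if (containment) {
      left_ok <- hits[idx, "q_start"] <= slack | hits[idx, "s_start"] <= slack
      right_ok <- hits[idx, "q_end"] >= ref_len - slack |
        hits[idx, "s_end"] >= read_len - slack
      qual <- qual & left_ok & right_ok
    }
    ok[idx] <- qual
  }
  if (!any(ok))
    return(list(verdict = "uninformative", best_reference = NA_character_,
                identity_pct = NA_real_, flank_up_cov = NA_real_,
                flank_down_cov = NA_real_, score = NA_real_))
  roles <- refs$role[hits[, "ref"]]
  best_t <- suppressWarnings(max(score[ok & roles == "template"]))
  best_r <- suppressWarnings(max(score[ok & roles == "recombinant"]))
  verdict <- if (best_r > best_t) "alternative"
  else if (best_t > best_r) "master"
  else "uninformative"
  b <- which(ok)[which.max(score[ok])]
  ri <- hits[b, "ref"]
  list(verdict = verdict, best_reference = refs$name[ri],
       identity_pct = 100 * hits[b, "matches"] / max(hits[b, "columns"], 1),
       flank_up_cov = max(0, refs$up_len[ri] - hits[b, "q_start"]),
       flank_down_cov = max(0, hits[b, "q_end"] -
                              (refs$up_len[ri] + refs$core_len[ri])),
       score = hits[b, "score"])
}

#' Classify one long read against a repeat pair's reference set
#'
#' Aligns the read (both strands) to every template and recombinant
#' reference. The best-scoring qualifying alignment - blast-style identity
#' at or above `min_identity` and alignment extension of at least
#' `min_flank` bp beyond both repeat boundaries into the flanks - sets the
#' verdict: a template gives `master`, a recombinant gives `alternative`.
#' No qualifying alignment, or equal best template and recombinant scores,
#' gives `uninformative` (ties are resolved conservatively, against calling
#' a recombinant).
#'
#' @param read a read sequence (character).
#' @param refset a [build_reference_set()] result.
#' @param min_identity identity threshold in percent (default 99.5).
#' @param min_flank required flank extension in bp (default 200).
#' @param word seed word size for read-vs-reference alignment (default 11).
#' @param scheme a [scoring_scheme()].
#' @return list with `verdict` (`master`/`alternative`/`uninformative`),
#'   `best_reference`, `identity_pct`, `flank_up_cov`, `flank_down_cov`,
#'   `score`.
#' @export
classify_read <- function(read, refset, min_identity = 99.5, min_flank = 200L,
                          word = 11L, scheme = scoring_scheme()) {
  hits <- map_read_to_refs(read, refset$refs, word, scheme,
                           classification_min_report(min_flank))
  judge_read(hits, refset$refs, nchar(read), min_identity, min_flank)
}

#' Re-validate alternative candidates with extended flanks
#'
#' Rebuilds the reference set with long flanks (default 2000 bp) and keeps a
#' candidate only if its best qualifying alignment against the extended set
#' is still to a recombinant reference. At this stage the alignment must
#' additionally cover the read's full overlap with the reference (alignment
#' ends within `slack` bp of whichever sequence ends first, on both sides):
#' a read whose agreement with the recombinant junction stops shortly beyond
#' the screening flank - the signature of a spurious match borrowed from
#' another repeat copy - is thereby demoted, while a true recombinant read
#' matches the alternative conformation along its whole length.
#'
#' @param candidates named character vector of reads with stage-1
#'   `alternative` verdicts.
#' @param genome the master [genome_sequence()].
#' @param pair the repeat pair row.
#' @param flank extended flank length (default 2000).
#' @param min_identity,min_flank,word,scheme as in [classify_read()].
#' @param slack end tolerance in bp for the containment requirement.
#' @return Character vector of surviving read ids.
#' @export
validate_with_extended_flanks <- function(candidates, genome, pair,
                                          flank = 2000L, min_identity = 99.5,
                                          min_flank = 200L, word = 11L,
                                          scheme = scoring_scheme(),
                                          slack = 30L) {
  if (length(candidates) == 0L) return(character(0))
  refset <- build_reference_set(genome, pair, flank = flank)
  keep <- vapply(candidates, function(r) {
    hits <- map_read_to_refs(r, refset$refs, word, scheme,
                             classification_min_report(min_flank))
    j <- judge_read(hits, refset$refs, nchar(r), min_identity, min_flank,
                    containment = TRUE, slack = slack)
    identical(j$verdict, "alternative")
  }, logical(1))
  names(candidates)[keep]
}

#' Per-pair recombination record from read verdicts
#'
#' @param pair the repeat pair row.
#' @param verdicts character vector of per-read verdicts (names are read
#'   ids; each read contributes at most once).
#' @return list with `pair_id`, `master_count`, `alt_count`,
#'   `frequency_pct` (`100 * alt / (alt + master)`, `NA` when no read is
#'   informative) and `recombined_read_ids`.
#' @export
summarize_recombination <- function(pair, verdicts) {
  ids <- names(verdicts)
  if (!is.null(ids) && anyDuplicated(ids))
    verdicts <- verdicts[!duplicated(ids)]
  m <- sum(verdicts == "master")
  a <- sum(verdicts == "alternative")
  freq <- if (m + a > 0) 100 * a / (a + m) else NA_real_
  list(pair_id = pair$id[1], master_count = m, alt_count = a,
       frequency_pct = freq,
       recombined_read_ids = names(verdicts)[verdicts == "alternative"])
}

format_position <- function(start0, end0, strand) {
  s1 <- format(start0 + 1L, big.mark = ",", scientific = FALSE, trim = TRUE)
  e1 <- format(end0, big.mark = ",", scientific = FALSE, trim = TRUE)
  if (strand == "-") paste0(e1, "-", s1) else paste0(s1, "-", e1)
}

#' Detect repeat-mediated recombination across a set of repeat pairs
#'
#' The full two-stage procedure for every pair: build the screening
#' reference set (200-bp flanks), classify every read, re-validate
#' `alternative` candidates against 2000-bp flanks, and summarise master and
#' alternative support with the recombination frequency
#' `100 * alt / (alt + master)`. Each pair is evaluated independently; a
#' read contributes at most one verdict per pair.
#'
#' @param genome master circular [genome_sequence()].
#' @param pairs data.frame of repeat pairs ([find_repeat_pairs()] layout).
#' @param reads named character vector of reads.
#' @param min_identity identity threshold in percent (default 99.5).
#' @param min_flank required flank extension (default 200).
#' @param flank screening flank (default 200).
#' @param validate_flank validation flank (default 2000).
#' @param word seed word size for classification (default 11).
#' @param scheme a [scoring_scheme()].
#' @return list with `summary` (data.frame: one row per pair with counts,
#'   percentages and printed 1-based positions, minus-strand copies printed
#'   with descending coordinates) and `verdicts` (data.frame of informative
#'   and stage-1 candidate verdicts: `read_id`, `pair_id`, `verdict`,
#'   `best_reference`, `identity_pct`, `stage`).
#' @export
detect_recombination <- function(genome, pairs, reads, min_identity = 99.5,
                                 min_flank = 200L, flank = 200L,
                                 validate_flank = 2000L, word = 11L,
                                 scheme = scoring_scheme()) {
  genome <- as_genome_sequence(genome)
  stopifnot(nrow(pairs) >= 1L, length(reads) >= 1L)
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  refsets <- lapply(seq_len(nrow(pairs)), function(i)
    build_reference_set(genome, pairs[i, ], flank = flank))
  all_refs <- do.call(rbind, lapply(refsets, function(rs) {
    r <- rs$refs; r$pair_id <- rs$pair_id; r
  }))
  group <- split(seq_len(nrow(all_refs)), all_refs$pair_id)
  min_report <- classification_min_report(min_flank)

  verdict_rows <- list()
  per_pair <- lapply(seq_len(nrow(pairs)), function(i) character(0))
  names(per_pair) <- pairs$id
  for (ri in seq_along(reads)) {
    hits <- map_read_to_refs(reads[[ri]], all_refs, word, scheme, min_report)
    if (all(hits[, "score"] == 0)) next
    rl <- nchar(reads[[ri]])
    for (pid in names(group)) {
      rows <- c(rbind(2L * group[[pid]] - 1L, 2L * group[[pid]]))
      sub <- hits[rows, , drop = FALSE]
      if (all(sub[, "score"] == 0)) next
      j <- judge_read(sub, all_refs, rl, min_identity, min_flank)
      if (j$verdict == "uninformative") next
      per_pair[[pid]] <- c(per_pair[[pid]],
                           structure(j$verdict, names = names(reads)[ri]))
      verdict_rows[[length(verdict_rows) + 1L]] <-
        data.frame(read_id = names(reads)[ri], pair_id = pid,
                   verdict = j$verdict, best_reference = j$best_reference,
                   identity_pct = j$identity_pct, stage = 1L,
                   stringsAsFactors = FALSE)
    }
  }

  summary_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    v <- per_pair[[p$id]]
    cand <- names(v)[v == "alternative"]
    if (length(cand)) {
      surv <- validate_with_extended_flanks(reads[cand], genome, p,
                                            flank = validate_flank,
                                            min_identity = min_identity,
                                            min_flank = min_flank,
                                            word = word, scheme = scheme)
      demoted <- setdiff(cand, surv)
      v[demoted] <- "uninformative"
      for (d in demoted)
        verdict_rows[[length(verdict_rows) + 1L]] <-
          data.frame(read_id = d, pair_id = p$id, verdict = "demoted",
                     best_reference = NA_character_, identity_pct = NA_real_,
                     stage = 2L, stringsAsFactors = FALSE)
    }
    rec <- summarize_recombination(p, v)
    n_inf <- rec$master_count + rec$alt_count
    summary_rows[[i]] <- data.frame(
      id = p$id, length = p$length, identity_pct = round(p$identity_pct, 2),
      orientation = if (isTRUE(p$palindromic)) "palindromic" else p$orientation,
      position_a = format_position(p$a_start, p$a_end, p$a_strand),
      position_b = format_position(p$b_start, p$b_end, p$b_strand),
      master_count = rec$master_count,
      master_pct = if (n_inf > 0) round(100 * rec$master_count / n_inf, 2) else NA_real_,
      alt_count = rec$alt_count,
      alt_pct = if (n_inf > 0) round(100 * rec$alt_count / n_inf, 2) else NA_real_,
      frequency_pct = if (n_inf > 0) round(rec$frequency_pct, 2) else NA_real_,
      recombined_read_ids = paste(rec$recombined_read_ids, collapse = ","),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  verdicts <- if (length(verdict_rows)) do.call(rbind, verdict_rows)
  else data.frame(read_id = character(), pair_id = character(),
                  verdict = character(), best_reference = character(),
                  identity_pct = numeric(), stage = integer(),
                  stringsAsFactors = FALSE)
  list(summary = summary, verdicts = verdicts)
}
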