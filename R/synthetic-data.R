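#' Specification of one planted repeat pair
#'
#' @param length repeat length in bp (>= 30, the analysis floor).
#' @param identity_pct target identity of the two copies, 80-100.
#' @param orientation `"direct"`, `"inverted"` or `"palindromic"` (a single
#'   locus aligning to its own reverse complement).
#' @param positions optional 0-based start positions of the two copies (one
#'   for a palindromic locus); `NULL` lets the builder place them.
#' @param label pair label.
#' @return An object of class `repeat_spec`.
#' @export
repeat_spec <- function(length, identity_pct = 100,
                        orientation = c("direct", "inverted", "palindromic"),
                        positions = NULL, label = NULL) {
  orientation <- match.arg(orientation)
  if (length < 30) stop("planted repeats must be at least 30 bp", call. = FALSE)
  if (identity_pct < 80 || identity_pct > 100)
    stop("identity_pct must be in [80, 100]", call. = FALSE)
  if (orientation == "palindromic" && length %% 2L != 0L)
    length <- length + 1L
  structure(list(length = as.integer(length), identity_pct = identity_pct,
                 orientation = orientation, positions = positions,
                 label = label),
            class = "repeat_spec")
}

#' Blueprint for a synthetic circular genome with planted repeats
#'
#' @param length genome length in bp.
#' @param gc_fraction background GC content (default 0.451, the typical GC
#'   of an early-angiosperm mitogenome).
#' @param repeats list of [repeat_spec()] objects.
#' @param plastid_shared_segments optional list of `c(length, identity_pct)`
#'   pairs: segments copied (with substitutions) from a companion plastid
#'   genome into the mitogenome, emulating plastid-derived inserts.
#' @param plastid_length length of the companion plastid genome (only used
#'   when shared segments are requested).
#' @param seed integer seed; fully determines the output.
#' @return An object of class `genome_blueprint`.
#' @export
genome_blueprint <- function(length, gc_fraction = 0.451, repeats = list(),
                             plastid_shared_segments = list(),
                             plastid_length = 30000L, seed = 1L) {
  if (length <= 0) stop("genome length must be positive", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]", call. = FALSE)
  planted <- sum(vapply(repeats, function(r)
    if (r$orientation == "palindromic") r$length else 2L * r$length, numeric(1)))
  if (planted >= length)
    stop("planted repeat material exceeds genome length", call. = FALSE)
  structure(list(length = as.integer(length), gc_fraction = gc_fraction,
                 repeats = repeats,
                 plastid_shared_segments = plastid_shared_segments,
                 plastid_length = as.integer(plastid_length),
                 seed = as.integer(seed)),
            class = "genome_blueprint")
}

random_dna <- function(n, gc = 0.451) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# substitute exactly k positions (to a different base each)
mutate_substitutions <- function(seq, k) {
  if (k <= 0L) return(seq)
  n <- nchar(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(bases, ch[p])
    ch[p] <- alt[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

#' Build a synthetic circular genome from a blueprint
#'
#' Generates an i.i.d. background at the configured GC, then plants each
#' repeat pair: copy A keeps the background sequence at its locus and copy B
#' is copy A with exactly `round((1 - identity/100) * length)` substitutions
#' scattered uniformly (reverse-complemented for inverted pairs). A
#' palindromic locus is `X` followed by a mutated reverse complement of `X`,
#' so the locus aligns to its own reverse complement at the planted
#' identity. Copies of each pair are interleaved around the circle so the
#' two copies of a pair are distant, as in real mitogenomes.
#'
#' @param blueprint a [genome_blueprint()].
#' @return list with `genome` (a [genome_sequence()]), `truth` (planted
#'   pairs in [find_repeat_pairs()] column layout), and, when plastid
#'   segments were requested, `plastid` (a [genome_sequence()]) and
#'   `plastid_truth` (data.frame of planted inserts).
#' @export
build_genome <- function(blueprint) {
  stopifnot(inherits(blueprint, "genome_blueprint"))
  set.seed(blueprint$seed)
  L <- blueprint$length
  seq <- random_dna(L, blueprint$gc_fraction)

  # one locus per palindromic spec, two otherwise; interleave a-copies then
  # b-copies so pair members are far apart
  specs <- blueprint$repeats
  loci <- list()
  for (i in seq_along(specs)) {
    r <- specs[[i]]
    lab <- if (is.null(r$label)) paste0("R", i) else r$label
    if (!is.null(r$positions)) {
      pos <- r$positions
      loci[[length(loci) + 1L]] <- list(pair = i, copy = "a", start = pos[1],
                                        len = r$length, label = lab)
      if (r$orientation != "palindromic")
        loci[[length(loci) + 1L]] <- list(pair = i, copy = "b", start = pos[2],
                                          len = r$length, label = lab)
    }
  }
  auto <- which(vapply(specs, function(r) is.null(r$positions), logical(1)))
  if (length(auto)) {
    order_copies <- c(lapply(auto, function(i) list(i = i, copy = "a")),
                      lapply(auto[vapply(specs[auto], function(r)
                        r$orientation != "palindromic", logical(1))],
                        function(i) list(i = i, copy = "b")))
    span <- sum(vapply(order_copies, function(x) specs[[x$i]]$length, numeric(1)))
    k <- length(order_copies)
    gap <- floor((L - 2000 - span) / max(k, 1L))
    if (gap < 50) stop("genome too small for the requested repeats", call. = FALSE)
    pos <- 1000L
    for (x in order_copies) {
      r <- specs[[x$i]]
      lab <- if (is.null(r$label)) paste0("R", x$i) else r$label
      loci[[length(loci) + 1L]] <- list(pair = x$i, copy = x$copy,
                                        start = pos, len = r$length, label = lab)
      pos <- pos + r$length + gap
    }
  }
  # overlap check
  if (length(loci) > 1L) {
    iv <- do.call(rbind, lapply(loci, function(l) c(l$start, l$start + l$len)))
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)]))
      stop("planted repeat copies overlap", call. = FALSE)
  }
  if (any(vapply(loci, function(l) l$start < 0 || l$start + l$len > L,
                 logical(1))))
    stop("planted repeat copy outside the genome", call. = FALSE)

  put <- function(seq, start, piece)
    paste0(substr(seq, 1L, start), piece, substr(seq, start + nchar(piece) + 1L, L))

  truth <- empty_pair_df()
  for (i in seq_along(specs)) {
    r <- specs[[i]]
    mine <- Filter(function(l) l$pair == i, loci)
    a <- mine[[which(vapply(mine, function(l) l$copy == "a", logical(1)))]]
    lab <- a$label
    if (r$orientation == "palindromic") {
      half <- r$length %/% 2L
      x <- substr(seq, a$start + 1L, a$start + half)
      k <- round((1 - r$identity_pct / 100) * r$length / 2)
      y <- mutate_substitutions(revcomp(x), k)
      seq <- put(seq, a$start, paste0(x, y))
      realized <- 100 * (r$length - 2 * k) / r$length
      truth <- rbind(truth, data.frame(
        id = lab, a_start = a$start, a_end = a$start + r$length, a_strand = "+",
        b_start = a$start, b_end = a$start + r$length, b_strand = "-",
        length = r$length, identity_pct = realized, orientation = "inverted",
        palindromic = TRUE, score = NA_integer_, evalue = NA_real_,
        stringsAsFactors = FALSE))
    } else {
      b <- mine[[which(vapply(mine, function(l) l$copy == "b", logical(1)))]]
      copy_a <- substr(seq, a$start + 1L, a$start + r$length)
      k <- round((1 - r$identity_pct / 100) * r$length)
      copy_b <- mutate_substitutions(copy_a, k)
      if (r$orientation == "inverted") copy_b <- revcomp(copy_b)
      seq <- put(seq, b$start, copy_b)
      realized <- 100 * (r$length - k) / r$length
      first <- if (a$start <= b$start) a else b
      second <- if (a$start <= b$start) b else a
      truth <- rbind(truth, data.frame(
        id = lab, a_start = first$start, a_end = first$start + r$length,
        a_strand = "+", b_start = second$start, b_end = second$start + r$length,
        b_strand = if (r$orientation == "inverted") "-" else "+",
        length = r$length, identity_pct = realized,
        orientation = r$orientation, palindromic = FALSE,
        score = NA_integer_, evalue = NA_real_, stringsAsFactors = FALSE))
    }
  }

  out <- list(genome = genome_sequence("synthetic_mito", seq, circular = TRUE),
              truth = truth)

  if (length(blueprint$plastid_shared_segments)) {
    plastid <- random_dna(blueprint$plastid_length, blueprint$gc_fraction)
    n_seg <- length(blueprint$plastid_shared_segments)
    mito_seq <- out$genome$seq
    # keep inserts away from planted repeats: place in the final 20% arc,
    # which the repeat placer leaves free of planted loci
    ins_pos <- floor(L * 0.82)
    pl_pos <- 500L
    pt <- data.frame(mito_start = integer(), mito_end = integer(),
                     plastid_start = integer(), plastid_end = integer(),
                     identity_pct = numeric(), stringsAsFactors = FALSE)
    for (sg in blueprint$plastid_shared_segments) {
      len <- as.integer(sg[[1]]); idp <- as.numeric(sg[[2]])
      if (pl_pos + len > blueprint$plastid_length || ins_pos + len > L - 200)
        stop("plastid segments do not fit", call. = FALSE)
      piece <- substr(plastid, pl_pos + 1L, pl_pos + len)
      k <- round((1 - idp / 100) * len)
      mito_seq <- paste0(substr(mito_seq, 1L, ins_pos),
                         mutate_substitutions(piece, k),
                         substr(mito_seq, ins_pos + len + 1L, L))
      pt <- rbind(pt, data.frame(mito_start = ins_pos, mito_end = ins_pos + len,
                                 plastid_start = pl_pos, plastid_end = pl_pos + len,
                                 identity_pct = 100 * (len - k) / len,
                                 stringsAsFactors = FALSE))
      ins_pos <- ins_pos + len + 500L
      pl_pos <- pl_pos + len + 500L
    }
    out$genome <- genome_sequence("synthetic_mito", mito_seq, circular = TRUE)
    out$plastid <- genome_sequence("synthetic_plastid", plastid, circular = TRUE)
    out$plastid_truth <- pt
  }
  out
}

#' Demo blueprint emulating a repeat-rich water-lily-like mitogenome
#'
#' Ten planted repeat pairs whose lengths and identities follow the ten
#' recombinationally active pairs reported for the *Nymphaea colorata*
#' mitogenome (3293/100 inverted, 128/82.8 palindromic, 462/100 direct,
#' 1538/97.3 inverted, 508/81.5 inverted, 399/99.7 direct, 945/98.4
#' inverted, 729/99.9 inverted, 692/99.9 inverted, 72/97.2 direct), planted
#' on a 100-kb circle at GC 45.1%. The circle is scaled down from the
#' 617-kb original so end-to-end runs take minutes, with geometry preserved.
#'
#' @param length genome length (default 1e5).
#' @param seed integer seed.
#' @return A [genome_blueprint()].
#' @export
demo_blueprint <- function(length = 100000L, seed = 42L) {
  spec <- list(
    repeat_spec(3293, 100.00, "inverted",    label = "R1"),
    repeat_spec(128,  82.81, "palindromic",  label = "R2"),
    repeat_spec(462,  100.00, "direct",      label = "R3"),
    repeat_spec(1538, 97.33, "inverted",     label = "R4"),
    repeat_spec(508,  81.50, "inverted",     label = "R5"),
    repeat_spec(399,  99.75, "direct",       label = "R6"),
    repeat_spec(945,  98.41, "inverted",     label = "R7"),
    repeat_spec(729,  99.86, "inverted",     label = "R8"),
    repeat_spec(692,  99.86, "inverted",     label = "R9"),
    repeat_spec(72,   97.22, "direct",       label = "R10"))
  genome_blueprint(length, gc_fraction = 0.451, repeats = spec, seed = seed)
}

#' Long-read simulation configuration
#'
#' Emulates an accuracy-corrected long-read pool: log-normal read lengths
#' around a configurable mean and a low per-base error rate. Defaults: mean
#' length 7294 bp, length dispersion sigma 0.4, depth 601x, and error rates
#' substitution 0.1%, insertion 0.05%, deletion 0.05% (total 0.2%, i.e.
#' accuracy 99.8%). Corrected long reads are well above 99.5% accuracy in
#' practice; the 2:1:1 substitution:insertion:deletion ratio exercises the
#' gapped alignment path.
#'
#' @param mean_len mean read length in bp.
#' @param len_sigma sdlog of the log-normal length law.
#' @param depth fold-coverage of the (master) genome; ignored if
#'   `read_count` is given.
#' @param read_count exact number of reads to simulate, overrides `depth`.
#' @param sub_rate,ins_rate,del_rate per-base error probabilities
#'   (total must be <= 0.05).
#' @param min_len shortest read emitted.
#' @param seed integer seed, `NULL` to use the current RNG state.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(mean_len = 7294, len_sigma = 0.4, depth = 601,
                            read_count = NULL, sub_rate = 0.001,
                            ins_rate = 0.0005, del_rate = 0.0005,
                            min_len = 200L, seed = NULL) {
  if (any(c(sub_rate, ins_rate, del_rate) < 0) ||
      sub_rate + ins_rate + del_rate > 0.05)
    stop("error rates must be >= 0 and total <= 0.05", call. = FALSE)
  if (is.null(read_count) && (is.null(depth) || depth <= 0))
    stop("depth must be positive (or give read_count)", call. = FALSE)
  structure(list(mean_len = mean_len, len_sigma = len_sigma, depth = depth,
                 read_count = read_count, sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 min_len = as.integer(min_len), seed = seed),
            class = "read_sim_config")
}

#' Simulate long reads from a mixture of circular conformations
#'
#' Read start positions are uniform on each circular conformation (reads may
#' wrap the origin), strands are equiprobable, lengths are log-normal with
#' the configured mean, and per-base errors are applied after extraction.
#' Provenance (source conformation, start, strand) is retained so tests can
#' use ground truth. Identical seeds give identical output.
#'
#' @param conformations list of entries `list(genome = , weight = )`, where
#'   `genome` is a [genome_sequence()] (or string) and `weight` a
#'   non-negative mixture weight. Names of the list name the conformations;
#'   unnamed entries are called `conf1`, `conf2`, ...
#' @param cfg a [read_sim_config()]. In depth mode the read count is
#'   `round(depth * length(first conformation) / mean_len)`.
#' @return list with `reads` (named character vector) and `provenance`
#'   (data.frame: `read_id`, `source`, `start`, `strand`, `true_len`).
#' @export
simulate_reads <- function(conformations, cfg = read_sim_config()) {
  if (length(conformations) == 0L)
    stop("at least one conformation is required", call. = FALSE)
  nms <- names(conformations)
  if (is.null(nms)) nms <- rep("", length(conformations))
  nms[!nzchar(nms)] <- paste0("conf", which(!nzchar(nms)))
  genomes <- lapply(seq_along(conformations), function(i)
    as_genome_sequence(conformations[[i]]$genome, nms[i]))
  w <- vapply(conformations, function(x) as.numeric(x$weight), numeric(1))
  if (any(w < 0) || sum(w) <= 0)
    stop("mixture weights must be non-negative with a positive sum", call. = FALSE)
  w <- w / sum(w)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- if (!is.null(cfg$read_count)) as.integer(cfg$read_count)
  else as.integer(round(cfg$depth * genomes[[1]]$length / cfg$mean_len))
  if (n <= 0L) stop("no reads requested", call. = FALSE)

  src <- sample.int(length(genomes), n, replace = TRUE, prob = w)
  meanlog <- log(cfg$mean_len) - cfg$len_sigma^2 / 2
  lens <- pmax(cfg$min_len, round(rlnorm(n, meanlog, cfg$len_sigma)))
  reads <- character(n)
  starts <- integer(n)
  strands <- character(n)
  for (i in seq_len(n)) {
    g <- genomes[[src[i]]]
    len <- min(lens[i], g$length)
    start <- floor(runif(1, 0, g$length))
    s <- circular_substr(g$seq, start, start + len)
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (strand == "-") s <- revcomp(s)
    if (cfg$sub_rate + cfg$ins_rate + cfg$del_rate > 0)
      s <- cpp_mutate_read(s, cfg$sub_rate, cfg$ins_rate, cfg$del_rate)
    reads[i] <- s
    starts[i] <- start
    strands[i] <- strand
    lens[i] <- len
  }
  ids <- sprintf("read%06d", seq_len(n))
  names(reads) <- ids
  list(reads = reads,
       provenance = data.frame(read_id = ids, source = nms[src],
                               start = starts, strand = strands,
                               true_len = lens, stringsAsFactors = FALSE))
}

#' Generate circular signed gene orders with planted conserved runs
#'
#' Builds one circular signed gene order per taxon. Planted runs are kept
#' contiguous (as a unit, possibly flipped) by treating each run as a single
#' block while applying random segment inversions; an inversion reverses the
#' segment and negates the signs of everything in it.
#'
#' @param n_taxa number of taxa.
#' @param n_genes total number of gene symbols (fillers named `g001`...).
#' @param planted_clusters list of character vectors of gene symbols; each
#'   run stays contiguous in every taxon.
#' @param shuffle_ops number of random inversions per taxon (scalar or
#'   vector of length `n_taxa`).
#' @param seed integer seed.
#' @return list of [gene_order()] objects named `taxon1`, `taxon2`, ...
#' @export
make_gene_orders <- function(n_taxa, n_genes, planted_clusters = list(),
                             shuffle_ops = 0L, seed = 1L) {
  set.seed(seed)
  planted <- unlist(planted_clusters)
  if (anyDuplicated(planted))
    stop("duplicate gene symbols in planted clusters", call. = FALSE)
  n_fill <- n_genes - length(planted)
  if (n_fill < 0) stop("planted runs do not fit within n_genes", call. = FALSE)
  fillers <- sprintf("g%03d", seq_len(n_fill))
  if (any(fillers %in% planted))
    stop("duplicate gene symbols", call. = FALSE)
  # block representation: each planted run is one block, fillers are singletons
  blocks <- c(planted_clusters, as.list(fillers))
  base <- sample(seq_along(blocks))
  if (length(shuffle_ops) == 1L) shuffle_ops <- rep(shuffle_ops, n_taxa)
  out <- list()
  for (t in seq_len(n_taxa)) {
    ord <- base
    sgn <- rep(1L, length(ord))
    for (op in seq_len(shuffle_ops[t])) {
      ij <- sort(sample.int(length(ord), 2L))
      i <- ij[1]; j <- ij[2]
      ord[i:j] <- rev(ord[i:j])
      sgn[i:j] <- -rev(sgn[i:j])
    }
    genes <- character(0)
    for (k in seq_along(ord)) {
      blk <- blocks[[ord[k]]]
      if (sgn[k] < 0) genes <- c(genes, paste0("-", rev(blk)))
      else genes <- c(genes, blk)
    }
    # normalise double negatives from flipped blocks of signed symbols
    genes <- sub("^--", "", genes)
    out[[paste0("taxon", t)]] <- gene_order(paste0("taxon", t), genes)
  }
  out
}
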