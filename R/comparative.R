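#' Detect plastid-derived inserts in a mitochondrial genome
#'
#' Searches the mitogenome against the plastid genome, keeps significant
#' hits above the length floor, merges hits that overlap on the
#' mitochondrial side into one insert locus (union extent; reported identity
#' is the length-weighted mean of the merged hits; the plastid interval is
#' taken from the longest merged hit), and sorts inserts by length,
#' descending. Per-hit unmerged output is available via `merge = FALSE`.
#'
#' @param mito,plastid [genome_sequence()] objects.
#' @param max_evalue e-value cut-off (default 1e-6).
#' @param word seed word size (default 7).
#' @param min_len minimum insert length in bp (default 30).
#' @param merge merge mito-side overlapping hits (default TRUE).
#' @param scheme a [scoring_scheme()].
#' @return data.frame with `mito_start`, `mito_end` (0-based half-open),
#'   `length`, `plastid_start`, `plastid_end`, `plastid_strand`,
#'   `identity_pct`, `n_hits`.
#' @export
find_plastid_inserts <- function(mito, plastid, max_evalue = 1e-6, word = 7L,
                                 min_len = 30L, merge = TRUE,
                                 scheme = scoring_scheme()) {
  mito <- as_genome_sequence(mito, "mito")
  plastid <- as_genome_sequence(plastid, "plastid")
  hits <- local_align_all(mito, plastid, min_word = word,
                          max_evalue = max_evalue, scheme = scheme)
  hits <- hits[hits$length >= min_len, , drop = FALSE]
  empty <- data.frame(mito_start = integer(), mito_end = integer(),
                      length = integer(), plastid_start = integer(),
                      plastid_end = integer(), plastid_strand = character(),
                      identity_pct = numeric(), n_hits = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$q_start, hits$q_end), , drop = FALSE]
  if (!merge) {
    out <- data.frame(mito_start = hits$q_start, mito_end = hits$q_end,
                      length = hits$q_end - hits$q_start,
                      plastid_start = hits$s_start, plastid_end = hits$s_end,
                      plastid_strand = hits$s_strand,
                      identity_pct = hits$identity_pct,
                      n_hits = 1L, stringsAsFactors = FALSE)
  } else {
    grp <- integer(nrow(hits))
    g <- 1L; grp[1] <- 1L; cur_end <- hits$q_end[1]
    for (i in seq_len(nrow(hits))[-1]) {
      if (hits$q_start[i] < cur_end) {
        grp[i] <- g
        cur_end <- max(cur_end, hits$q_end[i])
      } else {
        g <- g + 1L; grp[i] <- g; cur_end <- hits$q_end[i]
      }
    }
    out <- do.call(rbind, lapply(split(hits, grp), function(h) {
      w <- h$q_end - h$q_start
      best <- which.max(w)
      data.frame(mito_start = min(h$q_start), mito_end = max(h$q_end),
                 length = max(h$q_end) - min(h$q_start),
                 plastid_start = h$s_start[best], plastid_end = h$s_end[best],
                 plastid_strand = h$s_strand[best],
                 identity_pct = sum(h$identity_pct * w) / sum(w),
                 n_hits = nrow(h), stringsAsFactors = FALSE)
    }))
  }
  out <- out[order(-out$length, out$mito_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' A circular signed gene order
#'
#' @param taxon taxon label.
#' @param genes character vector of gene symbols in circular order; a
#'   leading `-` marks reverse orientation. Symbols must be unique
#'   (duplicated genes are rejected; drop or rename duplicates upstream).
#' @return An object of class `gene_order`.
#' @export
gene_order <- function(taxon, genes) {
  if (length(genes) < 2L) stop("a gene order needs at least two genes", call. = FALSE)
  sym <- sub("^-", "", genes)
  if (anyDuplicated(sym))
    stop(sprintf("duplicate gene symbols in '%s': %s", taxon,
                 paste(unique(sym[duplicated(sym)]), collapse = ", ")),
         call. = FALSE)
  structure(list(taxon = as.character(taxon), genes = as.character(genes)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s: %d genes (circular)\n", x$taxon,
              length(x$genes)))
  cat(" ", paste(head(x$genes, 12), collapse = " "),
      if (length(x$genes) > 12) "...\n" else "\n")
  invisible(x)
}

order_signs <- function(genes) ifelse(grepl("^-", genes), -1L, 1L)
order_syms <- function(genes) sub("^-", "", genes)

# adjacency set of a circular signed gene order: each gene g has extremities
# g.t (tail) and g.h (head); consecutive genes contribute one adjacency
adjacencies <- function(genes) {
  sym <- order_syms(genes); sgn <- order_signs(genes)
  n <- length(genes)
  right <- ifelse(sgn > 0, paste0(sym, ".h"), paste0(sym, ".t"))
  left <- ifelse(sgn > 0, paste0(sym, ".t"), paste0(sym, ".h"))
  nxt <- c(2:n, 1)
  adj <- cbind(right, left[nxt])
  t(apply(adj, 1, sort))
}

#' Double-cut-and-join (DCJ) distance between two circular gene orders
#'
#' Builds the adjacency graph of the two circular signed genomes over their
#' common markers and returns `n - c`, the number of markers minus the
#' number of cycles: the minimum number of double-cut-and-join operations
#' (inversions, translocations, excisions/reintegrations) transforming one
#' genome into the other.
#'
#' @param a,b [gene_order()] objects over the same gene set (signs free).
#' @return Integer DCJ distance.
#' @export
dcj_distance <- function(a, b) {
  sa <- order_syms(a$genes); sb <- order_syms(b$genes)
  if (!setequal(sa, sb) || length(sa) != length(sb)) {
    diffs <- c(setdiff(sa, sb), setdiff(sb, sa))
    stop(sprintf("gene sets differ; symmetric difference: %s",
                 paste(unique(diffs), collapse = ", ")), call. = FALSE)
  }
  adj_a <- adjacencies(a$genes)
  adj_b <- adjacencies(b$genes)
  n <- length(sa)
  # union graph: every extremity has degree 2 (one adjacency per genome);
  # count its cycles
  edges <- rbind(adj_a, adj_b)
  verts <- unique(as.vector(edges))
  vi <- seq_along(verts); names(vi) <- verts
  nb <- vector("list", length(verts))
  for (i in seq_len(nrow(edges))) {
    u <- vi[[edges[i, 1]]]; v <- vi[[edges[i, 2]]]
    nb[[u]] <- c(nb[[u]], v); nb[[v]] <- c(nb[[v]], u)
  }
  seen <- logical(length(verts))
  cycles <- 0L
  for (s in seq_along(verts)) {
    if (seen[s]) next
    cycles <- cycles + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, nb[[v]][!seen[nb[[v]]]])
    }
  }
  as.integer(n - cycles)
}

signed_run_key <- function(genes) paste(genes, collapse = " ")

flip_run <- function(genes) {
  flipped <- rev(genes)
  ifelse(grepl("^-", flipped), sub("^-", "", flipped), paste0("-", flipped))
}

canonical_run <- function(genes) {
  a <- signed_run_key(genes); b <- signed_run_key(flip_run(genes))
  if (a <= b) a else b
}

# does `ord` contain `run` contiguously (as a unit, possibly flipped)?
contains_run <- function(ord, run, signed = TRUE) {
  n <- length(ord$genes)
  if (length(run) > n) return(FALSE)
  doubled <- c(ord$genes, ord$genes)
  k <- length(run)
  probe <- function(x, target) {
    for (i in seq_len(n)) {
      w <- x[i:(i + k - 1)]
      if (signed) {
        if (identical(w, target)) return(TRUE)
      } else {
        if (identical(order_syms(w), order_syms(target))) return(TRUE)
      }
    }
    FALSE
  }
  probe(doubled, run) || probe(doubled, flip_run(run))
}

#' Conserved gene clusters across circular gene orders
#'
#' Reports maximal runs of two or more genes that appear contiguously, with
#' preserved internal order (the whole run may be flipped), in at least
#' `min_focal` of the focal taxa and in at least one taxon of at least one
#' outgroup group. Maximality: a run is dropped when a longer reported run
#' with identical focal and outgroup support contains it.
#'
#' @param orders named list of [gene_order()] objects.
#' @param focal character vector of focal taxon names (>= 2).
#' @param outgroups named list of character vectors grouping the remaining
#'   taxa (e.g. major plant lineages).
#' @param min_focal minimum number of focal taxa carrying the run
#'   (default 2).
#' @param signed require orientation (signs) to be preserved within the run
#'   (default TRUE); `FALSE` matches on gene adjacency regardless of
#'   orientation.
#' @return data.frame with `genes` (space-separated signed run), `length`,
#'   `focal_taxa`, `outgroup_taxa`.
#' @export
find_conserved_clusters <- function(orders, focal, outgroups,
                                    min_focal = 2L, signed = TRUE) {
  if (length(focal) < 2L) stop("need at least two focal taxa", call. = FALSE)
  missing_focal <- setdiff(focal, names(orders))
  if (length(missing_focal))
    stop(sprintf("unknown focal taxa: %s", paste(missing_focal, collapse = ", ")),
         call. = FALSE)
  # candidate runs: every circular window of every focal taxon
  cands <- new.env(parent = emptyenv())
  for (tx in focal) {
    g <- orders[[tx]]$genes
    n <- length(g)
    doubled <- c(g, g)
    for (len in 2:max(2, n - 1)) {
      if (len > n - 1) break
      for (i in seq_len(n)) {
        run <- doubled[i:(i + len - 1)]
        key <- canonical_run(run)
        if (!exists(key, envir = cands)) assign(key, run, envir = cands)
      }
    }
  }
  rows <- list()
  for (key in ls(cands)) {
    run <- get(key, envir = cands)
    in_focal <- focal[vapply(focal, function(tx)
      contains_run(orders[[tx]], run, signed), logical(1))]
    if (length(in_focal) < min_focal) next
    out_hits <- character(0)
    for (grp in names(outgroups)) {
      for (tx in outgroups[[grp]]) {
        if (!tx %in% names(orders)) next
        if (contains_run(orders[[tx]], run, signed)) out_hits <- c(out_hits, tx)
      }
    }
    if (length(out_hits) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      genes = paste(run, collapse = " "), length = length(run),
      focal_taxa = paste(sort(in_focal), collapse = ","),
      outgroup_taxa = paste(sort(unique(out_hits)), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(genes = character(), length = integer(),
                      focal_taxa = character(), outgroup_taxa = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  # maximality: drop runs contained in a longer run with identical support
  keep <- rep(TRUE, nrow(out))
  run_list <- strsplit(out$genes, " ", fixed = TRUE)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j || out$length[j] <= out$length[i]) next
      if (out$focal_taxa[i] != out$focal_taxa[j] ||
          out$outgroup_taxa[i] != out$outgroup_taxa[j]) next
      big <- run_list[[j]]; small <- run_list[[i]]
      ext <- c(big, big)
      hit <- FALSE
      for (s in seq_len(length(big))) {
        w <- ext[s:(s + length(small) - 1)]
        if (identical(w, small) || identical(w, flip_run(small)) ||
            (!signed && identical(order_syms(w), order_syms(small)))) {
          hit <- TRUE; break
        }
      }
      if (hit) { keep[i] <- FALSE; break }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$length, out$genes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene orders from plain text
#'
#' One taxon per line: the taxon label, whitespace, then comma-separated
#' signed gene symbols (e.g. `nymphaea rpl2,-rps19,rps3`).
#'
#' @param path text file.
#' @return Named list of [gene_order()] objects.
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    taxon <- parts[1]
    genes <- strsplit(paste(parts[-1], collapse = ""), ",", fixed = TRUE)[[1]]
    out[[taxon]] <- gene_order(taxon, trimws(genes))
  }
  out
}

#' Write gene orders to plain text
#'
#' @param orders named list of [gene_order()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(orders, path) {
  lines <- vapply(orders, function(o)
    paste(o$taxon, paste(o$genes, collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}
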