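# Independent oracles used across the suite. These are deliberately written
# with different algorithms than the package (bitmaps, shift scans, BFS,
# string surgery) so they can arbitrate.

random_seq <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# position-marking bitmap union of circular 0-based half-open intervals
bitmap_union <- function(starts, ends, L) {
  covered <- logical(L)
  for (i in seq_along(starts)) {
    s <- starts[i] %% L
    len <- ends[i] - starts[i]
    if (starts[i] > ends[i]) len <- ends[i] - starts[i] + L
    if (len >= L) return(L)
    pos <- (s + seq_len(len) - 1L) %% L
    covered[pos + 1L] <- TRUE
  }
  sum(covered)
}

# brute-force maximal exact repeats by scanning all shifts of the sequence
# against itself (direct) and against its reverse complement (inverted)
bf_exact_repeats <- function(seq, min_len) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  emit <- function(a_start, b_start, len, strand) {
    a <- c(a_start, a_start + len)
    b <- c(b_start, b_start + len)
    if (a[1] > b[1]) { tmp <- a; a <- b; b <- tmp }
    out[[length(out) + 1L]] <<- data.frame(
      a_start = a[1], a_end = a[2], b_start = b[1], b_end = b[2],
      len = len, strand = strand, stringsAsFactors = FALSE)
  }
  for (d in seq_len(n - 1)) {
    eq <- v[seq_len(n - d)] == v[seq_len(n - d) + d]
    r <- rle(eq)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len))
      emit(starts[k] - 1L, starts[k] - 1L + d, r$lengths[k], "+")
  }
  # inverted: v[x] == comp(v[y]) with x + y constant along an anti-diagonal
  for (s_sum in 2:(2 * n)) {
    x <- max(1L, s_sum - n):min(n, s_sum - 1L)
    y <- s_sum - x
    eq <- v[x] == unname(comp[v[y]])
    r <- rle(eq)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      x0 <- x[starts[k]]; l <- r$lengths[k]
      # segment A = [x0-1, x0-1+l); B is its reverse-complement partner
      y_hi <- s_sum - x0           # partner of the first position
      b_start <- y_hi - l          # 0-based
      emit(x0 - 1L, b_start, l, "-")
    }
  }
  if (!length(out)) return(data.frame())
  df <- do.call(rbind, out)
  df[!duplicated(df[, c("a_start", "a_end", "b_start", "b_end", "strand")]), ,
     drop = FALSE]
}

# hamming identity of equal-length strings (planted copies have no indels)
hamming_identity <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(va) == length(vb))
  100 * sum(va == vb) / length(va)
}

# --- BFS oracle for the DCJ distance ---------------------------------------
# A circular genome over n unique signed genes is a perfect matching on the
# 2n gene extremities (its adjacency set). A DCJ operation replaces two
# adjacencies {a,b},{c,d} by {a,c},{b,d} or {a,d},{b,c}. BFS over matchings.
oracle_adjacencies <- function(genes) {
  sym <- sub("^-", "", genes)
  sgn <- ifelse(grepl("^-", genes), -1L, 1L)
  n <- length(genes)
  right <- ifelse(sgn > 0, paste0(sym, ".h"), paste0(sym, ".t"))
  left <- ifelse(sgn > 0, paste0(sym, ".t"), paste0(sym, ".h"))
  adj <- cbind(right, left[c(2:n, 1)])
  apply(adj, 1, function(x) paste(sort(x), collapse = "|"))
}

state_key <- function(adjs) paste(sort(adjs), collapse = ";")

bfs_dcj_distance <- function(genes_a, genes_b, max_depth = 12L) {
  start <- oracle_adjacencies(genes_a)
  goal <- state_key(oracle_adjacencies(genes_b))
  if (state_key(start) == goal) return(0L)
  frontier <- list(start)
  seen <- new.env(parent = emptyenv())
  assign(state_key(start), TRUE, envir = seen)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (st in frontier) {
      m <- length(st)
      for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        e1 <- strsplit(st[i], "|", fixed = TRUE)[[1]]
        e2 <- strsplit(st[j], "|", fixed = TRUE)[[1]]
        for (variant in 1:2) {
          if (variant == 1) {
            na <- c(paste(sort(c(e1[1], e2[1])), collapse = "|"),
                    paste(sort(c(e1[2], e2[2])), collapse = "|"))
          } else {
            na <- c(paste(sort(c(e1[1], e2[2])), collapse = "|"),
                    paste(sort(c(e1[2], e2[1])), collapse = "|"))
          }
          cand <- c(st[-c(i, j)], na)
          key <- state_key(cand)
          if (key == goal) return(depth)
          if (!exists(key, envir = seen)) {
            assign(key, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- cand
          }
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  stop("BFS oracle exceeded max_depth")
}

random_signed_order <- function(n) {
  g <- paste0("g", seq_len(n))
  g <- sample(g)
  sgn <- sample(c("", "-"), n, replace = TRUE)
  paste0(sgn, g)
}

# exact binomial central 99% interval for the alternative count
binom99_bounds <- function(n, p) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p))
}
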