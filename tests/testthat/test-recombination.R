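toy_pair <- function(id, a, b, orientation, identity = 100, palindromic = FALSE) {
  data.frame(id = id, a_start = a[1], a_end = a[2], a_strand = "+",
             b_start = b[1], b_end = b[2],
             b_strand = if (orientation == "inverted") "-" else "+",
             length = a[2] - a[1], identity_pct = identity,
             orientation = orientation, palindromic = palindromic,
             score = NA_integer_, evalue = NA_real_, stringsAsFactors = FALSE)
}

test_that("direct-repeat recombination excises two subcircles (string-surgery oracle)", {
  set.seed(61)
  X <- random_seq(20); R <- random_seq(10); Y <- random_seq(15); Z <- random_seq(15)
  g <- genome_sequence("toy", paste0(X, R, Y, R, Z))
  pair <- toy_pair("T", c(20, 30), c(45, 55), "direct")
  alts <- apply_recombination(g, pair)
  expect_identical(length(alts), 2L)
  lens <- vapply(alts, function(x) x$length, numeric(1))
  expect_identical(sum(lens), 70)
  # junction strings from an independent cut-and-paste construction
  expect_identical(alts[[1]]$seq, paste0(R, Y))
  expect_identical(alts[[2]]$seq, paste0(R, Z, X))
  # base multiset conserved across the output set
  expect_identical(sort(strsplit(paste0(alts[[1]]$seq, alts[[2]]$seq), "")[[1]]),
                   sort(strsplit(g$seq, "")[[1]]))
})

test_that("inverted-repeat recombination inverts the intervening segment and is an involution", {
  set.seed(67)
  X <- random_seq(20); R <- random_seq(10); Y <- random_seq(15); Z <- random_seq(15)
  g <- genome_sequence("toy", paste0(X, R, Y, revcomp(R), Z))
  pair <- toy_pair("T", c(20, 30), c(45, 55), "inverted")
  alts <- apply_recombination(g, pair)
  expect_identical(length(alts), 1L)
  expect_identical(alts[[1]]$seq, paste0(X, R, revcomp(Y), revcomp(R), Z))
  # A+T and C+G content invariant under the strand flip of the segment
  count_at <- function(s) sum(strsplit(s, "")[[1]] %in% c("A", "T"))
  expect_identical(count_at(alts[[1]]$seq), count_at(g$seq))
  # identity-100 pairs: applying the same event again restores the master
  back <- apply_recombination(alts[[1]], pair)
  expect_identical(back[[1]]$seq, g$seq)
})

test_that("palindromic recombination is an in-place reverse complement", {
  set.seed(71)
  X <- random_seq(25); Z <- random_seq(25)
  S <- paste0("ACGTTGCA", "TGCAACGT")  # not equal to its own revcomp
  g <- genome_sequence("toy", paste0(X, S, Z))
  pair <- toy_pair("P", c(25, 41), c(25, 41), "inverted", identity = 85,
                   palindromic = TRUE)
  alts <- apply_recombination(g, pair)
  expect_identical(alts[[1]]$seq, paste0(X, revcomp(S), Z))
  expect_error(apply_recombination(g, toy_pair("O", c(25, 41), c(30, 46),
                                               "direct")), "overlap")
})

test_that("reference sets have the documented cardinality and geometry", {
  bp <- genome_blueprint(30000, repeats = list(
    repeat_spec(400, 100, "inverted", label = "I100"),
    repeat_spec(400, 100, "direct", label = "D100"),
    repeat_spec(400, 95, "inverted", label = "I95"),
    repeat_spec(300, 95, "direct", label = "D95")), seed = 73)
  built <- build_genome(bp)
  for (i in seq_len(nrow(built$truth))) {
    tr <- built$truth[i, ]
    rs <- build_reference_set(built$genome, tr, flank = 200)
    n_rec <- sum(rs$refs$role == "recombinant")
    expect_identical(sum(rs$refs$role == "template"), 2L)
    expect_identical(n_rec, if (tr$identity_pct >= 100) 2L else 4L)
    expect_true(all(nchar(rs$refs$seq) == tr$length + 400L))
  }
})

test_that("flanks wrap the circular origin and error on linear overrun", {
  set.seed(79)
  g <- genome_sequence("toy", random_seq(5000), circular = TRUE)
  pair <- toy_pair("W", c(50, 250), c(2550, 2750), "direct")
  rs <- build_reference_set(g, pair, flank = 200)
  # the upstream flank of copy A reaches across the origin
  expect_identical(substr(rs$refs$seq[rs$refs$name == "template_a"], 1, 200),
                   paste0(substr(g$seq, 4851, 5000), substr(g$seq, 1, 50)))
  glin <- genome_sequence("lin", g$seq, circular = FALSE)
  expect_error(build_reference_set(glin, pair, flank = 200), "overruns")
})

classify_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bp <- genome_blueprint(30000, repeats = list(
        repeat_spec(400, 90, "inverted", label = "I1")), seed = 83)
      cache <<- build_genome(bp)
    }
    cache
  }
})

test_that("reads are classified master / alternative / uninformative", {
  built <- classify_fixture()
  tr <- built$truth[1, ]
  rs <- build_reference_set(built$genome, tr, flank = 200)
  g2 <- paste0(built$genome$seq, built$genome$seq)
  # error-free master read spanning copy A with 800 bp on each side
  read_m <- substr(g2, tr$a_start - 800 + 1, tr$a_end + 800)
  cm <- classify_read(read_m, rs)
  expect_identical(cm$verdict, "master")
  expect_gte(cm$flank_up_cov, 200)
  # read simulated from the alternative conformation across the junction
  alt <- apply_recombination(built$genome, tr)[[1]]
  read_a <- substr(paste0(alt$seq, alt$seq), tr$a_start - 800 + 1, tr$a_end + 800)
  ca <- classify_read(read_a, rs)
  expect_identical(ca$verdict, "alternative")
  # minus-strand reads are equally informative
  expect_identical(classify_read(revcomp(read_a), rs)$verdict, "alternative")
  # read reaching only 150 bp into one flank is uninformative
  read_s <- substr(g2, tr$a_start - 150 + 1, tr$a_end + 800)
  expect_identical(classify_read(read_s, rs)$verdict, "uninformative")
})

test_that("extended-flank validation keeps true recombinants and demotes borrowed-flank artefacts", {
  bp <- genome_blueprint(30000, repeats = list(
    repeat_spec(400, 100, "direct", label = "D1")), seed = 89)
  built <- build_genome(bp)
  g <- built$genome$seq
  tr <- built$truth[1, ]
  # true recombinant read: 5 kb spanning the excision junction
  alt <- apply_recombination(built$genome, tr)[[2]]
  a2 <- paste0(alt$seq, alt$seq)
  read_true <- substr(a2, alt$length - 2500 + 1, alt$length + 2500)
  # artefact locus: 300 bp borrowed from upstream of copy B, the repeat, and
  # 300 bp from downstream of copy A, planted elsewhere in the master genome
  C <- paste0(substr(g, tr$b_start - 300 + 1, tr$b_start),
              substr(g, tr$a_start + 1, tr$a_end),
              substr(g, tr$a_end + 1, tr$a_end + 300))
  g2 <- genome_sequence("trap", paste0(substr(g, 1, 20000), C,
                                       substr(g, 20000 + nchar(C) + 1, nchar(g))))
  read_fp <- substr(g2$seq, 18001, 24000)
  rs <- build_reference_set(g2, tr, flank = 200)
  expect_identical(classify_read(read_true, rs)$verdict, "alternative")
  expect_identical(classify_read(read_fp, rs)$verdict, "alternative")  # stage-1 FP
  surv <- validate_with_extended_flanks(c(good = read_true, bad = read_fp),
                                        g2, tr, flank = 2000)
  expect_identical(surv, "good")
})

test_that("recombination summaries count distinct reads and guard empty input", {
  pair <- toy_pair("S", c(10, 20), c(50, 60), "direct")
  v <- setNames(c(rep("master", 5), rep("alternative", 2), "uninformative"),
                paste0("r", 1:8))
  s <- summarize_recombination(pair, v)
  expect_identical(s$master_count, 5L)
  expect_identical(s$alt_count, 2L)
  expect_equal(s$frequency_pct, 100 * 2 / 7)
  expect_identical(sort(s$recombined_read_ids), c("r6", "r7"))
  # duplicated read ids contribute once
  dup <- setNames(c("alternative", "alternative"), c("x", "x"))
  expect_identical(summarize_recombination(pair, dup)$alt_count, 1L)
  # zero denominator reported as not-applicable
  expect_true(is.na(summarize_recombination(pair, character(0))$frequency_pct))
  expect_equal(summarize_recombination(
    pair, setNames("master", "r"))$frequency_pct, 0)
})

test_that("the two-stage detector recovers a planted mixture end to end", {
  bp <- genome_blueprint(40000, repeats = list(
    repeat_spec(800, 100, "inverted", label = "I1")), seed = 97)
  built <- build_genome(bp)
  alt <- apply_recombination(built$genome, built$truth[1, ])[[1]]
  sim <- simulate_reads(
    list(master = list(genome = built$genome, weight = 0.8),
         alt_I1 = list(genome = alt, weight = 0.2)),
    read_sim_config(mean_len = 5000, depth = 60, seed = 101))
  rec <- detect_recombination(built$genome, built$truth, sim$reads)
  s <- rec$summary[1, ]
  expect_gt(s$master_count + s$alt_count, 30)
  expect_gt(s$alt_count, 0)
  # estimate near the planted 20% mixture
  expect_gt(s$frequency_pct, 8)
  expect_lt(s$frequency_pct, 35)
  # per-pair read uniqueness: one verdict per read and pair
  stage1 <- rec$verdicts[rec$verdicts$stage == 1L, ]
  expect_false(anyDuplicated(paste(stage1$read_id, stage1$pair_id)) > 0)
})
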