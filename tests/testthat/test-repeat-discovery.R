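built_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bp <- genome_blueprint(30000, repeats = list(
        repeat_spec(500, 100, "direct", label = "D1"),
        repeat_spec(400, 90, "inverted", label = "I1"),
        repeat_spec(200, 95, "direct", label = "D2"),
        repeat_spec(128, 82.81, "palindromic", label = "P1")), seed = 13)
      cache <<- build_genome(bp)
    }
    cache
  }
})

test_that("planted pairs are recovered with correct geometry", {
  built <- built_fixture()
  pairs <- find_repeat_pairs(built$genome)
  # every planted pair at identity >= 85 and length >= 50 recovered within 5 bp
  for (i in seq_len(nrow(built$truth))) {
    tr <- built$truth[i, ]
    if (tr$identity_pct < 85 || tr$length < 50) next
    hit <- pairs[abs(pairs$a_start - tr$a_start) <= 5 &
                   abs(pairs$a_end - tr$a_end) <= 5 &
                   abs(pairs$b_start - tr$b_start) <= 5 &
                   abs(pairs$b_end - tr$b_end) <= 5, ]
    expect_gte(nrow(hit), 1)
    expect_identical(hit$orientation[1], tr$orientation)
  }
  # palindromic locus flagged even at low identity
  expect_true(any(pairs$palindromic))
  pal <- pairs[pairs$palindromic, ][1, ]
  tr <- built$truth[built$truth$palindromic, ]
  expect_lte(abs(pal$a_start - tr$a_start), 8)
  expect_identical(pal$b_strand, "-")
})

test_that("identity-100 planted pair reports identity 100 and direct orientation", {
  bp <- genome_blueprint(10000, repeats = list(
    repeat_spec(500, 100, "direct", label = "D")), seed = 17)
  built <- build_genome(bp)
  pairs <- find_repeat_pairs(built$genome)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$identity_pct, 100)
  expect_identical(pairs$orientation, "direct")
})

test_that("raising the floors never increases the pair count", {
  built <- built_fixture()
  n_base <- nrow(find_repeat_pairs(built$genome))
  expect_lte(nrow(find_repeat_pairs(built$genome, min_len = 150)), n_base)
  expect_lte(nrow(find_repeat_pairs(built$genome, min_identity = 92)), n_base)
})

test_that("unique begin-end coordinate counting de-duplicates exactly", {
  a <- data.frame(q_start = c(10, 10, 50), q_end = c(40, 40, 90),
                  s_start = c(200, 200, 300), s_end = c(230, 230, 340),
                  s_strand = c("+", "+", "-"))
  expect_identical(count_unique_coordinates(a), 4L)
  # N disjoint planted exact pairs give 2N coordinates
  bp <- genome_blueprint(30000, repeats = list(
    repeat_spec(300, 100, "direct", label = "A"),
    repeat_spec(250, 100, "direct", label = "B"),
    repeat_spec(200, 100, "inverted", label = "C")), seed = 19)
  built <- build_genome(bp)
  pairs <- find_repeat_pairs(built$genome)
  expect_identical(count_unique_coordinates(pairs), 2L * nrow(pairs))
  # hash-set oracle on the raw pair table
  keys <- unique(c(paste(pairs$a_start, pairs$a_end, pairs$a_strand),
                   paste(pairs$b_start, pairs$b_end, pairs$b_strand)))
  expect_identical(count_unique_coordinates(pairs), length(keys))
})

test_that("union repeat content matches the bitmap oracle", {
  built <- built_fixture()
  pairs <- find_repeat_pairs(built$genome)
  uf <- repeat_union_fraction(built$genome, pairs)
  expect_identical(uf$union_bp,
                   as.integer(bitmap_union(c(pairs$a_start, pairs$b_start),
                                           c(pairs$a_end, pairs$b_end),
                                           built$genome$length)))
  expect_equal(uf$fraction, uf$union_bp / built$genome$length)
  expect_identical(repeat_union_fraction(built$genome, empty <- pairs[0, ])$union_bp, 0L)
})

test_that("palindromic copies are not double-counted in union coverage", {
  bp <- genome_blueprint(8000, repeats = list(
    repeat_spec(128, 83, "palindromic", label = "P")), seed = 23)
  built <- build_genome(bp)
  uf <- repeat_union_fraction(built$genome, built$truth)
  expect_identical(uf$union_bp, 128L)
})

test_that("greedy incremental clustering groups by identity to the representative", {
  set.seed(29)
  core <- random_seq(400)
  base <- paste0(core, random_seq(30))  # longest: becomes the representative
  fam1 <- c(a = base, b = mtrecomb:::mutate_substitutions(core, 40),
            c = mtrecomb:::mutate_substitutions(core, 60))
  far <- mtrecomb:::mutate_substitutions(core, 120)  # ~70% identity to core
  fams <- cluster_families(c(fam1, d = far))
  expect_identical(length(fams), 2L)
  sizes <- sort(vapply(fams, function(f) length(f$members), integer(1)))
  expect_identical(sizes, c(1L, 3L))
  # identical sequences collapse into one family
  k <- c(x = base, y = base, z = base)
  expect_identical(length(cluster_families(k)), 1L)
  # representative is the longest member
  mixed <- c(long = paste0(base, random_seq(100)), short = base)
  f2 <- cluster_families(mixed)
  expect_identical(f2[[1]]$representative, "long")
  # degenerate input: shorter than the word size
  expect_warning(f3 <- cluster_families(c(tiny = "ACG", ok = base)),
                 "shorter than word size")
  expect_identical(length(f3), 2L)
  expect_identical(length(cluster_families(character(0))), 0L)
})

test_that("feature repeat fractions follow the planted coverage", {
  built <- built_fixture()
  tr <- built$truth
  L <- built$genome$length
  d1 <- tr[tr$id == "D1", ]
  feats <- data.frame(
    name = c("inside", "outside", "part60"),
    start = c(d1$a_start + 50, d1$a_end + 600, d1$a_start - 200),
    end = c(d1$a_start + 250, d1$a_end + 800, d1$a_start + 300))
  res <- interval_repeat_fraction(tr, feats, L)
  expect_equal(res$fraction[res$name == "inside"], 1.0)
  expect_equal(res$fraction[res$name == "outside"], 0.0)
  expect_gte(res$fraction[res$name == "part60"], 0.58)
  expect_lte(res$fraction[res$name == "part60"], 0.62)
  expect_error(interval_repeat_fraction(tr, data.frame(
    name = "bad", start = 10, end = 5), L), "bad")
})

test_that("feature files in BED and GFF3 dialects load to the same intervals", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tintron1\t0\t+", bed)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tintron\t101\t200\t.\t+\t.\tID=intron1"), gff)
  fb <- read_features(bed)
  fg <- read_features(gff)
  expect_identical(fb$start, fg$start)
  expect_identical(fb$end, fg$end)
  expect_identical(fb$start, 100L)
  expect_identical(fb$end, 200L)
})
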