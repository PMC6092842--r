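test_that("revcomp is an involution over the genome alphabet", {
  expect_identical(revcomp("ACGTN"), "NACGT")
  expect_identical(revcomp("ACGT"), "ACGT")  # palindromic sequence
  set.seed(1)
  for (i in 1:5) {
    x <- random_seq(sample(10:500, 1))
    expect_identical(revcomp(revcomp(x)), x)
    expect_identical(nchar(revcomp(x)), nchar(x))
  }
  expect_error(revcomp("ACGU"), "position 4")
})

test_that("e-value follows the Karlin-Altschul form and its invariances", {
  sc <- scoring_scheme()
  # independent evaluation: lambda from the characteristic polynomial
  # 0.25*y^5 - y^3 + 0.75 = 0 with y = exp(lambda), largest real root > 1
  roots <- polyroot(c(0.75, 0, 0, -1, 0, 0.25))
  y <- Re(roots[abs(Im(roots)) < 1e-8 & Re(roots) > 1.0001])
  lambda_ind <- log(max(y))
  expect_equal(sc$lambda, lambda_ind, tolerance = 1e-6)
  expect_equal(evalue(100, 2000, 5000, sc),
               0.41 * 2000 * 5000 * exp(-lambda_ind * 100), tolerance = 1e-6)
  # monotone decreasing in score, linear in search space
  e <- evalue(c(50, 60, 70), 1e4, 1e4, sc)
  expect_true(all(diff(e) < 0))
  expect_equal(evalue(50, 1e4, 2e4, sc), 2 * evalue(50, 1e4, 1e4, sc))
  expect_equal(evalue(1e6, 1e4, 1e4, sc), 0)  # score -> +Inf limit
  expect_error(evalue(50, 0, 10, sc), "positive")
})

test_that("union_length handles overlap, wrap-around and matches a bitmap", {
  expect_identical(union_length(c(0, 5), c(10, 15), 100), 15L)
  expect_identical(union_length(c(90, 0), c(100, 5), 100), 15L)
  expect_identical(union_length(90, 5, 100), 15L)  # wrapped single interval
  expect_identical(union_length(integer(0), integer(0), 50), 0L)
  set.seed(42)
  for (rep in 1:3) {
    n <- 1000
    s <- sample(0:9999, n, replace = TRUE)
    len <- sample(1:400, n, replace = TRUE)
    expect_identical(union_length(s, s + len, 10000),
                     as.integer(bitmap_union(s, s + len, 10000)))
  }
  expect_error(union_length(0, 1, 0), "positive")
})

test_that("local alignment finds identity, reverse-complement and symmetric hits", {
  set.seed(11)
  g <- random_seq(1000)
  gs <- genome_sequence("g", g, circular = FALSE)
  a <- local_align_all(gs, gs)
  expect_true(any(a$q_start == 0 & a$q_end == 1000 & a$identity_pct == 100))

  seg <- substr(g, 301, 600)
  b <- local_align_all(revcomp(seg), gs)
  expect_identical(b$s_strand[1], "-")
  expect_identical(b$identity_pct[1], 100)
  expect_identical(c(b$s_start[1], b$s_end[1]), c(300L, 600L))

  # symmetry: swapping query and subject mirrors the intervals
  q2 <- random_seq(400)
  sub2 <- paste0(random_seq(150), substr(q2, 101, 350), random_seq(200))
  f <- local_align_all(q2, genome_sequence("s", sub2, circular = FALSE))
  r <- local_align_all(sub2, genome_sequence("q", q2, circular = FALSE))
  expect_identical(nrow(f), nrow(r))
  expect_identical(c(f$q_start[1], f$q_end[1]), c(r$s_start[1], r$s_end[1]))
  expect_identical(c(f$s_start[1], f$s_end[1]), c(r$q_start[1], r$q_end[1]))

  expect_error(local_align_all("", gs), "empty")
  expect_error(local_align_all("ACGTX", gs), "position 5")
})

test_that("alignments cover every brute-force maximal exact repeat", {
  set.seed(23)
  bg <- random_seq(2000)
  dup <- substr(bg, 101, 300)
  inv <- substr(bg, 501, 640)
  g <- paste0(substr(bg, 1, 1100), dup, substr(bg, 1301, 1500),
              revcomp(inv), substr(bg, 1641, 2000))
  mem <- bf_exact_repeats(g, 30)
  # the oracle itself must see both planted copies
  expect_true(any(mem$strand == "+" & mem$len >= 200))
  expect_true(any(mem$strand == "-" & mem$len >= 140))
  hits <- local_align_all(genome_sequence("g", g, circular = FALSE),
                          genome_sequence("g", g, circular = FALSE),
                          self = TRUE)
  for (i in seq_len(nrow(mem))) {
    m <- mem[i, ]
    covered <- any(
      (hits$q_start <= m$a_start & hits$q_end >= m$a_end &
         hits$s_start <= m$b_start & hits$s_end >= m$b_end &
         hits$s_strand == m$strand) |
      (hits$q_start <= m$b_start & hits$q_end >= m$b_end &
         hits$s_start <= m$a_start & hits$s_end >= m$a_end &
         hits$s_strand == m$strand))
    expect_true(covered, label = sprintf(
      "maximal exact repeat %d-%d / %d-%d (%s) contained in an alignment",
      m$a_start, m$a_end, m$b_start, m$b_end, m$strand))
  }
})

test_that("circular subjects are searched across the origin", {
  set.seed(31)
  g <- random_seq(3000)
  gs <- genome_sequence("g", g, circular = TRUE)
  # query spanning the origin
  q <- paste0(substr(g, 2801, 3000), substr(g, 1, 200))
  h <- local_align_all(q, gs)
  expect_gte(nrow(h), 1L)
  expect_identical(h$identity_pct[1], 100)
  expect_identical(h$s_start[1], 2800L)
  expect_identical(h$s_end[1] - h$s_start[1], 400L)
})
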