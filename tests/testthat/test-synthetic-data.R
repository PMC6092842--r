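test_that("planted repeat copies honour orientation and identity", {
  bp <- genome_blueprint(20000, repeats = list(
    repeat_spec(500, 100, "direct", label = "D"),
    repeat_spec(400, 100, "inverted", label = "I"),
    repeat_spec(1000, 90, "direct", label = "M")), seed = 2)
  built <- build_genome(bp)
  g <- built$genome$seq
  tr <- built$truth
  d <- tr[tr$id == "D", ]
  expect_identical(substr(g, d$a_start + 1, d$a_end),
                   substr(g, d$b_start + 1, d$b_end))
  i <- tr[tr$id == "I", ]
  expect_identical(substr(g, i$b_start + 1, i$b_end),
                   revcomp(substr(g, i$a_start + 1, i$a_end)))
  m <- tr[tr$id == "M", ]
  ident <- hamming_identity(substr(g, m$a_start + 1, m$a_end),
                            substr(g, m$b_start + 1, m$b_end))
  expect_gte(ident, 88); expect_lte(ident, 92)
  expect_equal(m$identity_pct, ident)
})

test_that("palindromic loci align to their own reverse complement at the planted identity", {
  bp <- genome_blueprint(10000, repeats = list(
    repeat_spec(128, 82.81, "palindromic", label = "P")), seed = 9)
  built <- build_genome(bp)
  p <- built$truth[1, ]
  locus <- substr(built$genome$seq, p$a_start + 1, p$a_end)
  ident <- hamming_identity(locus, revcomp(locus))
  expect_gte(ident, 80.81); expect_lte(ident, 84.81)
})

test_that("blueprints are deterministic and reject impossible layouts", {
  bp <- genome_blueprint(15000, repeats = list(
    repeat_spec(300, 95, "inverted", label = "A")), seed = 7)
  expect_identical(build_genome(bp)$genome$seq, build_genome(bp)$genome$seq)
  expect_error(genome_blueprint(1000, repeats = list(
    repeat_spec(600, 100, "direct"))), "exceeds")
  expect_error(build_genome(genome_blueprint(5000, repeats = list(
    repeat_spec(300, 100, "direct", positions = c(1000, 1100))), seed = 1)),
    "overlap")
})

test_that("simulated reads carry faithful provenance and error-free reads are substrings", {
  bp <- genome_blueprint(12000, seed = 5)
  g <- build_genome(bp)$genome
  cfg <- read_sim_config(mean_len = 2000, read_count = 60, sub_rate = 0,
                         ins_rate = 0, del_rate = 0, seed = 21)
  sim <- simulate_reads(list(master = list(genome = g, weight = 1)), cfg)
  expect_true(all(sim$provenance$source == "master"))
  doubled <- paste0(g$seq, g$seq)
  for (i in seq_along(sim$reads)) {
    r <- sim$reads[[i]]
    if (sim$provenance$strand[i] == "-") r <- revcomp(r)
    expect_true(grepl(r, doubled, fixed = TRUE))
  }
  expect_error(simulate_reads(list(a = list(genome = g, weight = 0)), cfg),
               "weights")
})

test_that("read length and depth laws hold at simulation scale", {
  bp <- genome_blueprint(50000, seed = 6)
  g <- build_genome(bp)$genome
  cfg <- read_sim_config(mean_len = 7294, len_sigma = 0.4, read_count = 4000,
                         seed = 8)
  sim <- simulate_reads(list(master = list(genome = g, weight = 1)), cfg)
  # sample mean within 3 standard errors of the configured mean
  sd_ln <- 7294 * sqrt(exp(0.4^2) - 1)
  se <- sd_ln / sqrt(4000)
  expect_lt(abs(mean(sim$provenance$true_len) - 7294), 3 * se)
  # depth mode conserves total bases within 5%
  cfg2 <- read_sim_config(mean_len = 3000, depth = 40, seed = 12)
  sim2 <- simulate_reads(list(master = list(genome = g, weight = 1)), cfg2)
  expect_lt(abs(sum(nchar(sim2$reads)) - 40 * g$length) / (40 * g$length), 0.05)
})

test_that("identical seeds reproduce the read pool exactly", {
  g <- build_genome(genome_blueprint(8000, seed = 3))$genome
  cfg <- read_sim_config(mean_len = 1500, read_count = 40, seed = 33)
  s1 <- simulate_reads(list(master = list(genome = g, weight = 1)), cfg)
  s2 <- simulate_reads(list(master = list(genome = g, weight = 1)), cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$provenance, s2$provenance)
})

test_that("gene order generation keeps planted runs contiguous", {
  run <- c("rpl2", "rps19", "rps3", "rpl16")
  orders <- make_gene_orders(3, 30, planted_clusters = list(run),
                             shuffle_ops = 0, seed = 4)
  expect_identical(orders$taxon1$genes, orders$taxon2$genes)
  orders <- make_gene_orders(4, 30, planted_clusters = list(run),
                             shuffle_ops = 100, seed = 4)
  for (o in orders) {
    sym <- sub("^-", "", o$genes)
    doubled <- c(sym, sym)
    found <- FALSE
    for (i in seq_along(sym)) {
      w <- doubled[i:(i + 3)]
      if (identical(w, run) || identical(w, rev(run))) { found <- TRUE; break }
    }
    expect_true(found, label = sprintf("run contiguous in %s", o$taxon))
  }
  expect_error(make_gene_orders(2, 10,
                                planted_clusters = list(c("a", "b"), c("b", "c")),
                                seed = 1), "duplicate")
})

test_that("shuffling bounds the DCJ distance by the number of applied inversions", {
  orders <- make_gene_orders(2, 15, shuffle_ops = c(3, 4), seed = 10)
  d <- dcj_distance(orders$taxon1, orders$taxon2)
  expect_lte(d, 7)
})
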