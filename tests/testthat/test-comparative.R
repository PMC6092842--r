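test_that("planted plastid segments are recovered as merged inserts", {
  bp <- genome_blueprint(30000, repeats = list(),
                         plastid_shared_segments = list(c(1000, 85),
                                                        c(500, 100)),
                         plastid_length = 20000, seed = 103)
  built <- build_genome(bp)
  ins <- find_plastid_inserts(built$genome, built$plastid)
  expect_gte(nrow(ins), 2L)
  for (i in seq_len(nrow(built$plastid_truth))) {
    tr <- built$plastid_truth[i, ]
    hit <- ins[abs(ins$mito_start - tr$mito_start) <= 5 &
                 abs(ins$mito_end - tr$mito_end) <= 5, ]
    expect_gte(nrow(hit), 1L)
    expect_lte(abs(hit$identity_pct[1] - tr$identity_pct), 2)
  }
  # exact shared segment reports identity 100 at full length
  exact <- ins[abs(ins$identity_pct - 100) < 1e-9, ]
  expect_gte(nrow(exact), 1L)
  expect_identical(exact$length[1], 500L)
  # sorted by length descending, mito intervals disjoint after merging
  expect_true(all(diff(ins$length) <= 0))
  o <- ins[order(ins$mito_start), ]
  if (nrow(o) > 1) expect_true(all(o$mito_start[-1] >= o$mito_end[-nrow(o)]))
})

test_that("unrelated genomes yield no inserts", {
  set.seed(107)
  a <- genome_sequence("a", random_seq(20000))
  b <- genome_sequence("b", random_seq(20000))
  expect_identical(nrow(find_plastid_inserts(a, b)), 0L)
})

test_that("DCJ distance is zero on identity and one per inversion", {
  a <- gene_order("a", c("g1", "g2", "g3", "g4", "g5"))
  expect_identical(dcj_distance(a, a), 0L)
  b <- gene_order("b", c("g1", "-g3", "-g2", "g4", "g5"))  # one segment inverted
  expect_identical(dcj_distance(a, b), 1L)
  expect_error(dcj_distance(a, gene_order("c", c("g1", "g2", "g3", "g4", "gX"))),
               "g5")
})

test_that("DCJ distance satisfies the metric axioms on random circular orders", {
  set.seed(109)
  for (trial in 1:200) {
    n <- sample(3:8, 1)
    base <- paste0("g", seq_len(n))
    go <- function(genes) gene_order("t", genes)
    x <- go(random_signed_order(n))
    y <- go(random_signed_order(n))
    z <- go(random_signed_order(n))
    expect_identical(dcj_distance(x, x), 0L)
    expect_identical(dcj_distance(x, y), dcj_distance(y, x))
    expect_lte(dcj_distance(x, z), dcj_distance(x, y) + dcj_distance(y, z))
  }
})

test_that("conserved gene clusters are found in focal taxa with outgroup support", {
  run <- c("rpl2", "rps19", "rps3", "rpl16")
  orders <- make_gene_orders(5, 24, planted_clusters = list(run),
                             shuffle_ops = 40, seed = 113)
  names(orders) <- c("nymphaea", "amborella", "liriodendron", "fern", "moss")
  for (i in seq_along(orders)) orders[[i]]$taxon <- names(orders)[i]
  cl <- find_conserved_clusters(
    orders, focal = c("nymphaea", "amborella", "liriodendron"),
    outgroups = list(ferns = "fern", bryophytes = "moss"))
  found <- vapply(strsplit(cl$genes, " "), function(g) {
    s <- sub("^-", "", g)
    identical(s, run) || identical(s, rev(run))
  }, logical(1))
  expect_true(any(found))
  # adding an outgroup taxon never removes a reported cluster
  orders2 <- c(orders, list(extra = make_gene_orders(
    1, 24, planted_clusters = list(run), shuffle_ops = 40, seed = 127)[[1]]))
  orders2$extra$taxon <- "extra"
  cl2 <- find_conserved_clusters(
    orders2, focal = c("nymphaea", "amborella", "liriodendron"),
    outgroups = list(ferns = "fern", bryophytes = c("moss", "extra")))
  expect_true(all(cl$genes %in% cl2$genes))
  expect_error(find_conserved_clusters(orders, focal = c("nymphaea", "oak"),
                                       outgroups = list(f = "fern")),
               "oak")
})

test_that("runs flipped as a unit are still detected, with no support from disjoint orders", {
  o1 <- gene_order("t1", c("a", "b", "c", "d", "e", "f"))
  o2 <- gene_order("t2", c("-c", "-b", "-a", "e", "d", "f"))  # a b c flipped
  o3 <- gene_order("t3", c("a", "b", "c", "f", "e", "d"))
  cl <- find_conserved_clusters(list(t1 = o1, t2 = o2, t3 = o3),
                                focal = c("t1", "t2"),
                                outgroups = list(out = "t3"))
  expect_true("a b c" %in% cl$genes)
  # orders sharing no adjacency yield nothing
  p1 <- gene_order("p1", c("a", "b", "c", "d"))
  p2 <- gene_order("p2", c("a", "c", "b", "d"))
  p3 <- gene_order("p3", c("b", "a", "d", "c"))
  cl0 <- find_conserved_clusters(list(p1 = p1, p2 = p2, p3 = p3),
                                 focal = c("p1", "p2"),
                                 outgroups = list(out = "p3"))
  expect_identical(nrow(cl0), 0L)
})

test_that("gene orders round-trip through the plain-text format", {
  orders <- list(
    nymphaea = gene_order("nymphaea", c("rpl2", "-rps19", "rps3")),
    amborella = gene_order("amborella", c("rps3", "rpl2", "rps19")))
  path <- tempfile(fileext = ".txt")
  write_gene_orders(orders, path)
  back <- read_gene_orders(path)
  expect_identical(names(back), names(orders))
  expect_identical(back$nymphaea$genes, orders$nymphaea$genes)
})
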