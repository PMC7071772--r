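test_that("haplotype collapse conserves counts per population", {
  mat <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(1, 0, 1))
  haps <- haplotype_matrix(mat, c("a", "b", "c"), c(10, 20, 30),
                           c("YRI", "YRI", "CEU", "CEU"))
  nodes <- collapse_haplotypes(haps)
  expect_equal(nodes$bits, c("000", "101"))
  expect_equal(nodes$count_YRI, c(2L, 0L))
  expect_equal(nodes$count_CEU, c(1L, 1L))
  expect_equal(sum(nodes$count_total), 4L)

  set.seed(6)
  big <- matrix(rbinom(500 * 6, 1, 0.5), nrow = 500)
  bh <- haplotype_matrix(big, paste0("s", 1:6), 1:6,
                         sample(c("YRI", "CHB"), 500, replace = TRUE))
  bn <- collapse_haplotypes(bh)
  expect_equal(sum(bn$count_total), 500L)
  expect_false(any(duplicated(bn$bits)))
})

test_that("median_vector is the site-wise majority and distance minimizer", {
  expect_equal(median_vector("011", "101", "110"), "111")
  expect_equal(median_vector("0101", "0101", "1110"), "0101")
  expect_error(median_vector("01", "011", "010"), "equal length")

  set.seed(13)
  for (len in c(2, 4, 7, 10, 12)) {
    strs <- replicate(3, paste0(sample(0:1, len, replace = TRUE),
                                collapse = ""))
    m <- median_vector(strs[1], strs[2], strs[3])
    cost <- hamming_str(m, strs[1]) + hamming_str(m, strs[2]) +
      hamming_str(m, strs[3])
    expect_equal(cost, oracle_min_triple_cost(strs[1], strs[2], strs[3]))
  }
})

test_that("basic network shapes are as expected", {
  # two nodes at Hamming distance k: one edge of weight k
  net <- build_mj_network(c("0000", "0111"))
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(net$edges$weight, 3)

  one <- build_mj_network("1010")
  expect_equal(nrow(one$nodes), 1L)
  expect_equal(nrow(one$edges), 0L)

  # the classic quartet: the median 111 links the three weight-2 nodes
  cube <- build_mj_network(c("000", "011", "101", "110"))
  expect_true("111" %in% cube$nodes$bits)
  i111 <- which(cube$nodes$bits == "111")
  nb <- c(cube$edges$j[cube$edges$i == i111],
          cube$edges$i[cube$edges$j == i111])
  expect_true(all(c("011", "101", "110") %in% cube$nodes$bits[nb]))

  expect_error(build_mj_network(c("00", "000")), "length")
  expect_error(build_mj_network(c("00", "00")), "duplicate")
})

test_that("networks are connected with exact Hamming edge weights", {
  set.seed(23)
  for (k in 1:25) {
    len <- sample(3:8, 1)
    n <- sample(2:6, 1)
    bits <- unique(replicate(n, paste0(sample(0:1, len, replace = TRUE),
                                       collapse = "")))
    net <- build_mj_network(bits)
    g <- as_igraph_mj(net)
    expect_true(igraph::is_connected(g))
    for (e in seq_len(nrow(net$edges))) {
      expect_equal(net$edges$weight[e],
                   hamming_str(net$nodes$bits[net$edges$i[e]],
                               net$nodes$bits[net$edges$j[e]]))
    }
    expect_true(all(net$edges$weight >= 1))
    # medians carry zero counts; observed nodes keep theirs
    expect_true(all(net$nodes$count_total[net$nodes$is_median] == 0))
  }
})

test_that("unit-distance inputs reduce to the minimum spanning network", {
  # all pairwise distances 1: no medians, complete unit graph
  net <- build_mj_network(c("00", "01"))
  expect_equal(nrow(net$nodes), 2L)
  net2 <- build_mj_network(c("000", "001", "011"))
  # chain 000-001-011: weight-1 links only, median of the triple exists
  # already (001), so nothing is added
  expect_equal(sum(net2$nodes$is_median), 0L)
  expect_equal(sort(net2$edges$weight), c(1, 1))
})

test_that("construction is deterministic and permutation-isomorphic", {
  set.seed(77)
  bits <- unique(replicate(6, paste0(sample(0:1, 6, replace = TRUE),
                                     collapse = "")))
  a <- build_mj_network(bits)
  b <- build_mj_network(bits)
  expect_identical(a, b)
  p <- build_mj_network(rev(bits))
  expect_identical(a$nodes$bits, p$nodes$bits)  # canonical node order
  expect_identical(a$edges, p$edges)
})

test_that("exports round-trip and are byte-identical across runs", {
  haps <- simulate_haplotypes(n_hap_per_pop = 30, n_sites = 5, block = 1:5,
                              seed = 2)
  net <- build_mj_network(collapse_haplotypes(haps))
  f1 <- tempfile(fileext = ".graphml")
  f2 <- tempfile(fileext = ".graphml")
  export_network(net, f1)
  export_network(net, f2)
  expect_identical(readLines(f1), readLines(f2))

  g <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(sort(igraph::V(g)$name), sort(net$nodes$bits))
  expect_equal(sum(igraph::V(g)$count_total), 90)  # conservation

  dotf <- tempfile(fileext = ".dot")
  export_network(net, dotf, "dot")
  expect_true(file.exists(dotf) && length(readLines(dotf)) > 0)

  ntab <- tempfile(fileext = ".tsv")
  write_node_table(net, ntab)
  tab <- read.delim(ntab)
  expect_equal(sum(tab$count_total), 90)
})

test_that("small networks embed a minimal Steiner tree of the haplotypes", {
  set.seed(41)
  for (k in 1:12) {
    len <- sample(3:6, 1)
    bits <- unique(replicate(4, paste0(sample(0:1, len, replace = TRUE),
                                       collapse = "")))
    net <- build_mj_network(bits)
    terminals <- match(bits, net$nodes$bits)
    got <- graph_steiner_length(nrow(net$nodes), net$edges, terminals)
    want <- oracle_steiner_length(bits)
    expect_equal(got, want)
  }
})
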