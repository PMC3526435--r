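test_that("gene orientation distinguishes strands and telomeres", {
  g <- genome(c("p", "q"), c(1, -1))
  expect_equal(gene_sign(g, 1), 1L)
  expect_equal(gene_sign(g, 2), -1L)
  expect_equal(gene_sign(g, 0), 0L)
  expect_equal(gene_sign(g, 3), 0L)
})

test_that("consecutiveness ignores unsaturated genes", {
  g1 <- genome(c("a", "b", "c", "d"), rep(1L, 4), "G1")
  g2 <- genome(c("w", "x", "y", "z"), rep(1L, 4), "G2")
  sim <- similarity_matrix(c("a", "b", "d"), c("w", "x", "z"),
                           c(0.9, 0.9, 0.9))
  gr <- build_graph(g1, g2, sim)  # c / y pruned; positions shift
  m <- matching(gr, data.frame(i = c(1, 3), k = c(1, 3)))
  expect_true(is_consecutive(m, 1, 1, 3))   # pos 2 (b) unsaturated
  expect_true(is_consecutive(m, 1, 1, 2))   # adjacent positions
  m2 <- matching(gr, data.frame(i = 1:3, k = 1:3))
  expect_false(is_consecutive(m2, 1, 1, 3)) # pos 2 saturated now
  expect_error(is_consecutive(m, 1, 3, 1), "i < j")
  # randomized agreement with a direct scan
  for (seed in 1:5) {
    inst <- small_instance(seed, n_genes = 6)
    bf <- brute_force_optimum(inst$graph, 0.5)$matching
    sat <- c(0L, bf$edges$i, inst$graph$n1)
    for (i in 0:(inst$graph$n1 - 1L)) {
      for (j in (i + 1L):inst$graph$n1) {
        expect_equal(is_consecutive(bf, 1, i, j),
                     !any(sat > i & sat < j))
      }
    }
  }
})

test_that("conserved adjacency sign conditions cover all orientations", {
  # worked case: (2, -3) against (6, -7), parallel orientation
  g1 <- genome(c("g2", "g3"), c(1, -1), "G1")
  g2 <- genome(c("g6", "g7"), c(1, -1), "G2")
  sim <- similarity_matrix(c("g2", "g3"), c("g6", "g7"), c(0.9, 0.9))
  gr <- build_graph(g1, g2, sim)
  m <- matching(gr, data.frame(i = 1:2, k = 1:2))
  expect_true(is_conserved_adjacency(m, 1, 2, 1, 2))
  # flipped second sign violates condition 1
  g2b <- genome(c("g6", "g7"), c(1, 1), "G2")
  grb <- build_graph(g1, g2b, sim)
  mb <- matching(grb, data.frame(i = 1:2, k = 1:2))
  expect_false(is_conserved_adjacency(mb, 1, 2, 1, 2))
  expect_error(is_conserved_adjacency(m, 1, 2, 1, 1), "k != l")

  # exhaustive k > l sign table: adjacency iff both sign pairs differ
  for (s1 in c(-1L, 1L)) for (s2 in c(-1L, 1L)) {
    for (t1 in c(-1L, 1L)) for (t2 in c(-1L, 1L)) {
      ga <- genome(c("u", "v"), c(s1, s2), "GA")
      gb <- genome(c("w", "x"), c(t1, t2), "GB")
      simx <- similarity_matrix(c("u", "v"), c("x", "w"), c(0.8, 0.8))
      grx <- build_graph(ga, gb, simx)
      # cross matching: u-x (k=2), v-w (l=1), so k > l
      mx <- matching(grx, data.frame(i = c(1, 2), k = c(2, 1)))
      expect_equal(is_conserved_adjacency(mx, 1, 2, 2, 1),
                   (s1 != t2) && (s2 != t1))
    }
  }
})

test_that("toy instance reproduces the frozen objective values", {
  m <- toy_a_matching()
  adjs <- conserved_adjacencies(m)
  expect_equal(nrow(adjs), 4L)
  expect_equal(adj_weight(m), 2.88, tolerance = 1e-12)
  expect_equal(edg_weight(m), 3.94, tolerance = 1e-12)
  ob <- f_alpha(m, 0.5)
  expect_equal(ob$f_alpha, 3.41, tolerance = 1e-12)
  expect_equal(f_alpha(m, 1)$f_alpha, 2.88, tolerance = 1e-12)
  expect_equal(delta_distance(m), 0)
  # telomeric adjacency mixes weight 1 with the gene edge weight
  expect_equal(adjacency_score(m, 0, 1, 0, 1), 0.9)
  expect_equal(adjacency_score(m, 3, 4, 3, 4), 0.7)
  expect_error(f_alpha(m, 0), "alpha")
  expect_error(f_alpha(m, 1.2), "alpha")
})

test_that("scores agree with direct enumeration over random matchings", {
  for (seed in 1:15) {
    inst <- small_instance(seed)
    gr <- inst$graph
    for (alpha in c(0.3, 1)) {
      m <- brute_force_optimum(gr, alpha)$matching
      oracle <- naive_adjacency_score(m)
      expect_equal(adj_weight(m), oracle$adj, tolerance = 1e-9)
      expect_equal(adj_count(m), oracle$n_adj)
    }
    # planted matchings too (arbitrary, not optimal)
    oracle <- naive_adjacency_score(inst$planted)
    expect_equal(adj_weight(inst$planted), oracle$adj, tolerance = 1e-9)
  }
})

test_that("unit weights collapse weighted scores onto counts", {
  g1 <- genome(c("a", "b", "c"), c(1, 1, 1), "G1")
  g2 <- genome(c("x", "y", "z"), c(1, 1, 1), "G2")
  sim <- similarity_matrix(c("a", "b", "c"), c("x", "y", "z"), rep(1, 3))
  gr <- build_graph(g1, g2, sim)
  m <- matching(gr, data.frame(i = 1:3, k = 1:3))
  expect_equal(edg_weight(m), edg_count(m))
  expect_equal(adj_weight(m), adj_count(m))
  expect_equal(edg_count(m), 5L)  # m gene edges plus two telomere edges
})

test_that("degenerate and anti-correlated matchings bound the distance", {
  # all genes pruned: telomere-only matching, one telomeric adjacency
  g1 <- genome("a", 1, "G1")
  g2 <- genome("x", 1, "G2")
  gr <- build_graph(g1, g2, similarity_matrix())
  m <- matching(gr)
  expect_equal(adj_count(m), 1L)
  expect_equal(edg_count(m), 2L)
  expect_warning(d <- delta_distance(m), "degenerate")
  expect_equal(d, 0)
  # reversed order, same signs, crossed telomeres: zero adjacencies,
  # Delta = (m + 1) / (m + 2)
  ga <- genome(c("a", "b", "c"), c(1, 1, 1), "GA")
  gb <- genome(c("c2", "b2", "a2"), c(1, 1, 1), "GB")
  sim <- similarity_matrix(c("a", "b", "c"), c("a2", "b2", "c2"),
                           rep(1, 3))
  grx <- build_graph(ga, gb, sim)
  mx <- matching(grx, data.frame(i = 1:3, k = 3:1), telomeres = "crossed")
  expect_equal(adj_count(mx), 0L)
  expect_equal(delta_distance(mx), 4 / 5)
})

test_that("intermediate validity requires one edge per component", {
  g1 <- genome(c("a", "b"), c(1, 1), "G1")
  g2 <- genome(c("x", "y"), c(1, 1), "G2")
  sim <- similarity_matrix(c("a", "b"), c("x", "y"), c(0.5, 0.5))
  gr <- build_graph(g1, g2, sim)  # two components
  expect_false(is_valid_intermediate(matching(gr, data.frame(i = 1, k = 1))))
  expect_true(is_valid_intermediate(
    matching(gr, data.frame(i = 1:2, k = 1:2))))
  # randomized agreement with a direct component scan
  for (seed in 1:5) {
    inst <- small_instance(seed)
    gr <- inst$graph
    if (nrow(gr$edges) == 0L) next
    set.seed(seed)
    take <- sort(sample.int(nrow(gr$edges),
                            sample.int(nrow(gr$edges), 1L)))
    ed <- gr$edges[take, , drop = FALSE]
    ed <- ed[!duplicated(ed$i) & !duplicated(ed$k), , drop = FALSE]
    m <- matching(gr, ed[, c("i", "k")])
    scan <- all(seq_len(gr$n_comp) %in% unique(gr$comp1[ed$i]))
    expect_equal(is_valid_intermediate(m), scan)
  }
})

test_that("brute force dominates explicit feasible matchings", {
  for (seed in 1:25) {
    inst <- small_instance(seed)
    gr <- inst$graph
    alpha <- c(0.3, 0.5, 1)[seed %% 3 + 1]
    best <- brute_force_optimum(gr, alpha)
    expect_true(is_valid_intermediate(best$matching))
    # the planted matching is feasible, so never better than the optimum
    expect_gte(best$objective$f_alpha + 1e-9,
               f_alpha(inst$planted, alpha)$f_alpha)
    # forced single-edge components are always saturated
    fx <- preprocess_two_gene_components(gr)
    if (length(fx$forced_edges)) {
      key <- paste(best$matching$edges$i, best$matching$edges$k)
      expect_true(all(paste(fx$i, fx$k) %in% key))
    }
  }
})

test_that("full reversal of one genome preserves the optimum", {
  for (seed in 1:8) {
    inst <- small_instance(seed, n_genes = 5, noise_edges = 1)
    g2r <- genome(rev(inst$g2$ids), rev(-inst$g2$signs), "G2r")
    gr1 <- inst$graph
    gr2 <- build_graph(inst$g1, g2r, inst$sigma)
    for (alpha in c(0.3, 1)) {
      f1 <- brute_force_optimum(gr1, alpha)$objective$f_alpha
      f2 <- brute_force_optimum(gr2, alpha)$objective$f_alpha
      expect_equal(f1, f2, tolerance = 1e-9)
    }
  }
})

test_that("delta is symmetric in the genome order", {
  for (seed in 1:6) {
    inst <- small_instance(seed)
    gr12 <- inst$graph
    gr21 <- build_graph(inst$g2, inst$g1, inst$sigma)
    d12 <- delta_distance(brute_force_optimum(gr12, 0.5)$matching)
    d21 <- delta_distance(brute_force_optimum(gr21, 0.5)$matching)
    expect_equal(d12, d21, tolerance = 1e-9)
  }
})

test_that("matching serialization records pairs and adjacency membership", {
  m <- toy_a_matching()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_matching(m, tf)
  tab <- utils::read.table(tf, sep = "\t", header = TRUE)
  expect_equal(nrow(tab), 5L)  # 3 gene edges + 2 telomere rows
  expect_equal(sum(tab$gene_id_1 == "o"), 2L)
  expect_true(all(tab$in_adjacency == 1L))
})
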