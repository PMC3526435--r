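# Shared fixtures and independent oracles.

# Worked toy: two 3-gene genomes with a parallel one-to-one similarity.
# Frozen expectations (verified by exhaustive enumeration in
# test-matching-model.R): adj = 2.88, edg = 3.94, F_0.5 = 3.41, delta = 0.
toy_a <- function() {
  g1 <- genome(c("t1", "t2", "t3"), c(1, 1, -1), "T1")
  g2 <- genome(c("t4", "t5", "t6"), c(1, 1, -1), "T2")
  sim <- similarity_matrix(c("t1", "t2", "t3"), c("t4", "t5", "t6"),
                           c(0.9, 0.8, 0.7))
  build_graph(g1, g2, sim)
}

toy_a_matching <- function(gr = toy_a()) {
  matching(gr, data.frame(i = 1:3, k = 1:3))
}

# small simulated instance used across randomized tests
small_instance <- function(seed, n_genes = 6, n_inversions = 2,
                           n_duplications = 1, n_losses = 1,
                           noise_edges = 2) {
  simulate_pair(simulation_config(
    n_genes = n_genes, n_inversions = n_inversions,
    n_duplications = n_duplications, n_losses = n_losses,
    noise_edges = noise_edges, seed = seed))
}

# family-structured instance: unit weights, clique components (the
# classical gene-family setting the weighted model generalizes)
family_instance <- function(seed) {
  set.seed(1000 + seed)
  n_fam <- sample(3:4, 1L)
  mem1 <- pmin(1L + stats::rbinom(n_fam, 1L, 0.3), 2L)
  mem2 <- pmin(1L + stats::rbinom(n_fam, 1L, 0.3), 2L)
  ids1 <- unlist(lapply(seq_len(n_fam), function(ff) {
    sprintf("f%d_a%d", ff, seq_len(mem1[ff]))
  }))
  ids2 <- unlist(lapply(seq_len(n_fam), function(ff) {
    sprintf("f%d_b%d", ff, seq_len(mem2[ff]))
  }))
  fam1 <- rep(seq_len(n_fam), mem1)
  fam2 <- rep(seq_len(n_fam), mem2)
  o1 <- sample(length(ids1))
  o2 <- sample(length(ids2))
  g1 <- genome(ids1[o1], sample(c(-1L, 1L), length(ids1), TRUE), "G1")
  g2 <- genome(ids2[o2], sample(c(-1L, 1L), length(ids2), TRUE), "G2")
  pairs <- expand.grid(a = seq_along(ids1), b = seq_along(ids2))
  pairs <- pairs[fam1[pairs$a] == fam2[pairs$b], ]
  sim <- similarity_matrix(ids1[pairs$a], ids2[pairs$b],
                           rep(1, nrow(pairs)))
  build_graph(g1, g2, sim)
}

# independent union-find over an edge list, for component oracle checks
uf_components <- function(n_vertices, edges_from, edges_to) {
  parent <- seq_len(n_vertices)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_along(edges_from)) {
    a <- find(edges_from[r]); b <- find(edges_to[r])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n_vertices), find, integer(1))
}

# adjacency oracle: scores a matching straight from the definitions, by
# enumerating ordered pairs of matching edges (any other quadruple has an
# edge outside M and scores 0) and checking consecutiveness by direct scan
naive_adjacency_score <- function(m) {
  g <- m$graph
  tp <- if (m$telomeres == "parallel") c(0L, g$n2) else c(g$n2, 0L)
  rows <- rbind(data.frame(i = 0L, k = tp[1L], w = 1),
                data.frame(i = m$edges$i, k = m$edges$k, w = m$edges$w),
                data.frame(i = g$n1, k = tp[2L], w = 1))
  sat1 <- rows$i
  sat2 <- rows$k
  sgn1 <- function(p) if (p == 0L || p == g$n1) 0L else g$g1$signs[p]
  sgn2 <- function(p) if (p == 0L || p == g$n2) 0L else g$g2$signs[p]
  sign_ok <- function(sa, sb, par) {
    sa == 0L || sb == 0L || (if (par) sa == sb else sa != sb)
  }
  total <- 0
  count <- 0L
  for (r1 in seq_len(nrow(rows))) {
    for (r2 in seq_len(nrow(rows))) {
      i <- rows$i[r1]; j <- rows$i[r2]
      if (i >= j) next
      k <- rows$k[r1]; l <- rows$k[r2]
      if (any(sat1 > i & sat1 < j)) next
      if (any(sat2 > min(k, l) & sat2 < max(k, l))) next
      par <- k < l
      if (!sign_ok(sgn1(i), sgn2(k), par)) next
      if (!sign_ok(sgn1(j), sgn2(l), par)) next
      total <- total + rows$w[r1] * rows$w[r2]
      count <- count + 1L
    }
  }
  list(adj = total, n_adj = count)
}

# independent enumeration of heuristic candidate runs via run-length DP
scan_candidates <- function(graph, st1, st2, alpha) {
  n1g <- graph$n1 - 1L
  n2g <- graph$n2 - 1L
  W <- matrix(0, max(n1g, 1L), max(n2g, 1L))
  if (nrow(graph$edges)) W[cbind(graph$edges$i, graph$edges$k)] <-
      graph$edges$w
  nxt1 <- function(i) {
    p <- i + 1L
    while (p <= n1g && st1[p] != 0L) p <- p + 1L
    if (p <= n1g) p else NA_integer_
  }
  step2 <- function(k, dir) {
    p <- k + dir
    while (p >= 1L && p <= n2g && st2[p] != 0L) p <- p + dir
    if (p >= 1L && p <= n2g) p else NA_integer_
  }
  prv1 <- function(i) {
    p <- i - 1L
    while (p >= 1L && st1[p] != 0L) p <- p - 1L
    if (p >= 1L) p else NA_integer_
  }
  good <- function(i, k, rev_) {
    !is.na(i) && !is.na(k) && st1[i] == 0L && st2[k] == 0L &&
      W[i, k] > 0 &&
      (if (rev_) graph$g1$signs[i] == -graph$g2$signs[k]
       else graph$g1$signs[i] == graph$g2$signs[k])
  }
  out <- list()
  for (rev_ in c(FALSE, TRUE)) {
    dir <- if (rev_) -1L else 1L
    for (i in seq_len(n1g)) {
      for (k in seq_len(n2g)) {
        if (!good(i, k, rev_)) next
        if (good(prv1(i), step2(k, -dir), rev_)) next
        ii <- i; kk <- k
        ws <- W[ii, kk]
        while (good(nxt1(ii), step2(kk, dir), rev_)) {
          ii <- nxt1(ii); kk <- step2(kk, dir)
          ws <- c(ws, W[ii, kk])
        }
        out[[length(out) + 1L]] <- list(
          start1 = i, start2 = k, length = length(ws),
          orientation = if (rev_) "reversed" else "forward",
          score = alpha * sum(ws[-length(ws)] * ws[-1L]) +
            (1 - alpha) * sum(ws^2))
      }
    }
  }
  out
}

cand_key <- function(cands) {
  sort(vapply(cands, function(cc) {
    sprintf("%s:%d:%d:%d:%.9f", cc$orientation, cc$start1, cc$start2,
            cc$length, cc$score)
  }, character(1)))
}

# random additive (ultrametric-free) distance matrix from a random binary
# topology, for NJ recovery checks
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.2, 1))
  D <- ape::cophenetic.phylo(tr)
  o <- sample(n_taxa)
  list(tree = tr, D = D[o, o])
}
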