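heur_state <- function(graph) ffadj:::new_heuristic_state(graph)

test_that("identical genomes yield one spanning forward candidate", {
  ids <- sprintf("g%d", 1:5)
  signs <- c(1L, -1L, 1L, 1L, -1L)
  g1 <- genome(ids, signs, "G1")
  g2 <- genome(sprintf("h%d", 1:5), signs, "G2")
  sim <- similarity_matrix(ids, sprintf("h%d", 1:5), rep(0.9, 5))
  gr <- build_graph(g1, g2, sim)
  cands <- ffadj:::enumerate_candidates(heur_state(gr), 0.5)
  spans <- Filter(function(cc) cc$length == 5L, cands)
  expect_length(spans, 1L)
  expect_equal(spans[[1]]$orientation, "forward")
  expect_equal(spans[[1]]$start1, 1L)
})

test_that("a fully reversed genome yields one spanning reversed candidate", {
  ids <- sprintf("g%d", 1:5)
  signs <- c(1L, -1L, 1L, 1L, -1L)
  g1 <- genome(ids, signs, "G1")
  g2 <- genome(sprintf("h%d", 5:1), rev(-signs), "G2")
  sim <- similarity_matrix(ids, sprintf("h%d", 1:5), rep(0.9, 5))
  gr <- build_graph(g1, g2, sim)
  cands <- ffadj:::enumerate_candidates(heur_state(gr), 0.5)
  spans <- Filter(function(cc) cc$length == 5L, cands)
  expect_length(spans, 1L)
  expect_equal(spans[[1]]$orientation, "reversed")
})

test_that("candidate enumeration agrees with an independent scan", {
  for (seed in 1:10) {
    inst <- small_instance(seed, n_genes = 8, n_duplications = 2,
                           noise_edges = 3)
    gr <- inst$graph
    st <- heur_state(gr)
    ours <- ffadj:::enumerate_candidates(st, 0.5)
    theirs <- scan_candidates(gr, st$st1, st$st2, 0.5)
    expect_equal(cand_key(ours), cand_key(theirs))
  }
})

test_that("selection maximizes the local score with a lexicographic tie rule", {
  mk <- function(start1, start2, orientation, score) {
    list(start1 = start1, start2 = start2, length = 1L,
         orientation = orientation, pairs = matrix(c(start1, start2), 1),
         score = score)
  }
  # a short high-weight run can beat a long low-weight run under the
  # alpha-weighted local score
  long_run <- mk(3, 3, "forward", 0.5 * (2 * 0.09) + 0.5 * (3 * 0.09))
  short_run <- mk(5, 1, "forward", 0.5 * 0.81 + 0.5 * (2 * 0.81))
  expect_equal(ffadj:::select_mcs(list(long_run, short_run))$start1, 5)
  # ties: smallest start1, then start2, forward before reversed
  a <- mk(2, 4, "forward", 1)
  b <- mk(2, 2, "forward", 1)
  cc <- mk(1, 9, "reversed", 1)
  expect_equal(ffadj:::select_mcs(list(a, b, cc))$start1, 1)
  d <- mk(2, 2, "reversed", 1)
  expect_equal(ffadj:::select_mcs(list(a, d, b))$orientation, "forward")
  expect_equal(ffadj:::select_mcs(list(a))$start2, 4)
  expect_error(ffadj:::select_mcs(list()), "no candidates")
})

test_that("hopeless genes are deleted, genes with live partners kept", {
  g1 <- genome(c("a", "b"), c(1, 1), "G1")
  g2 <- genome(c("x", "y", "z"), c(1, 1, 1), "G2")
  sim <- similarity_matrix(c("a", "a", "b"), c("x", "y", "y"),
                           c(0.9, 0.4, 0.8))
  gr <- build_graph(g1, g2, sim)  # z pruned already
  st <- heur_state(gr)
  # match a-x; y keeps partner b, so only nothing else is hopeless yet
  st$st1[1] <- 1L; st$st2[1] <- 1L; st$partner1[1] <- 1L
  del <- ffadj:::delete_hopeless_genes(st)
  expect_equal(sum(del), 0L)
  # now match b-y: no unmatched partners remain anywhere
  st$st1[2] <- 1L; st$st2[2] <- 1L; st$partner1[2] <- 2L
  del2 <- ffadj:::delete_hopeless_genes(st)
  expect_equal(sum(del2), 0L)  # everything is matched, nothing to delete
  # fixed point equals an exhaustive recheck on random states
  for (seed in 1:6) {
    inst <- small_instance(seed)
    st <- heur_state(inst$graph)
    set.seed(seed)
    if (nrow(inst$graph$edges)) {
      r <- inst$graph$edges[sample.int(nrow(inst$graph$edges), 1L), ]
      st$st1[r$i] <- 1L; st$st2[r$k] <- 1L; st$partner1[r$i] <- r$k
    }
    ffadj:::delete_hopeless_genes(st)
    # after the fixed point, every unmatched gene has an unmatched partner
    un1 <- which(st$st1 == 0L)
    un2 <- which(st$st2 == 0L)
    for (i in un1) expect_true(any(st$W[i, un2] > 0))
    for (k in un2) expect_true(any(st$W[un1, k] > 0))
  }
})

test_that("deletion of an interrupting gene lets extension complete a run", {
  g1 <- genome(c("d", "a", "b", "c"), rep(1L, 4), "G1")
  g2 <- genome(c("d2", "a2", "x2", "b2", "c2"), rep(1L, 5), "G2")
  sim <- similarity_matrix(
    c("d", "a", "b", "c", "d"),
    c("d2", "a2", "b2", "c2", "x2"),
    c(0.9, 0.9, 0.9, 0.9, 0.8))
  gr <- build_graph(g1, g2, sim)
  res <- run_heuristic(gr, 0.5)
  # the hopeless interrupter x2 is deleted after the first run is matched,
  # and the run is completed across it: the final matching is the full
  # uninterrupted diagonal
  key <- paste(res$matching$edges$i, res$matching$edges$k)
  expect_setequal(key, c("1 1", "2 2", "3 4", "4 5"))
  expect_equal(adj_count(res$matching), 5L)
  expect_equal(delta_distance(res$matching), 0)
})

test_that("extension never pairs zero-similarity flanks", {
  # same layout but without the d-x2 edge: x2 is pruned at graph build,
  # so the diagonal run is unbroken from the start
  g1 <- genome(c("d", "a"), c(1L, 1L), "G1")
  g2 <- genome(c("d2", "a2"), c(1L, -1L), "G2")  # sign blocks extension
  sim <- similarity_matrix(c("d", "a"), c("d2", "a2"), c(0.9, 0.9))
  gr <- build_graph(g1, g2, sim)
  res <- run_heuristic(gr, 0.5)
  # both pairs matched as two separate length-1 runs (signs differ)
  expect_equal(nrow(res$matching$edges), 2L)
  expect_true(is_valid_intermediate(res$matching))
})

test_that("the heuristic equals the exact optimum on the toy", {
  for (alpha in c(0.3, 0.5, 1)) {
    h <- run_heuristic(toy_a(), alpha)
    ex <- solve_exact(toy_a(), alpha)
    expect_equal(h$objective$f_alpha, ex$objective$f_alpha,
                 tolerance = 1e-9)
    expect_equal(nrow(h$matching$edges), 3L)
  }
})

test_that("identical genomes give a perfect heuristic matching", {
  inst <- small_instance(11, n_inversions = 0, n_duplications = 0,
                         n_losses = 0, noise_edges = 0)
  res <- run_heuristic(inst$graph, 0.5)
  expect_equal(delta_distance(res$matching), 0)
})

test_that("the heuristic never exceeds the exact optimum and saturates", {
  for (seed in 1:25) {
    inst <- small_instance(seed)
    gr <- inst$graph
    alpha <- c(0.001, 0.3, 0.5, 0.8, 1)[seed %% 5 + 1]
    h <- run_heuristic(gr, alpha)
    ex <- solve_exact(gr, alpha)
    expect_lte(h$objective$f_alpha, ex$objective$f_alpha + 1e-9)
    expect_true(is_valid_intermediate(h$matching))
    # full saturation: no positive-similarity edge between unmatched genes
    un1 <- setdiff(seq_len(gr$n1 - 1L), h$matching$edges$i)
    un2 <- setdiff(seq_len(gr$n2 - 1L), h$matching$edges$k)
    leftover <- gr$edges$i %in% un1 & gr$edges$k %in% un2
    expect_false(any(leftover))
  }
})

test_that("at alpha 1 the heuristic keeps the matching large", {
  # family-structured instances (unit weights, clique components): the
  # exact solver may drop isolated pairs at alpha 1; the full-saturation
  # heuristic does not
  for (seed in 1:10) {
    gr <- family_instance(seed)
    h <- run_heuristic(gr, 1)
    ex <- solve_exact(gr, 1)
    expect_gte(edg_weight(h$matching) + 1e-9, edg_weight(ex$matching))
  }
})
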