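# Lean scorer for a selection of gene edges (positions must come sorted by
# i, vertex-disjoint). Returns c(adj_weight, edg_weight, adj_count).
# Shares the adjacency semantics of conserved_adjacency_table() but avoids
# building matching objects inside enumeration loops.
score_selection <- function(g, ei, ek, ew, crossed) {
  n1 <- g$n1; n2 <- g$n2
  p_first <- if (crossed) n2 else 0L
  p_last <- if (crossed) 0L else n2
  s1 <- c(0L, ei, n1)
  pk <- c(p_first, ek, p_last)
  pw <- c(1, ew, 1)
  s2 <- sort(c(0L, ek, n2))
  rk <- match(pk, s2)
  adjw <- 0
  adjc <- 0L
  sg1 <- g$g1$signs
  sg2 <- g$g2$signs
  for (t in seq_len(length(s1) - 1L)) {
    if (abs(rk[t] - rk[t + 1L]) != 1L) next
    par <- pk[t] < pk[t + 1L]
    i <- s1[t]; j <- s1[t + 1L]; k <- pk[t]; l <- pk[t + 1L]
    si <- if (i == 0L || i == n1) 0L else sg1[i]
    sk <- if (k == 0L || k == n2) 0L else sg2[k]
    if (!(si == 0L || sk == 0L || (if (par) si == sk else si != sk))) next
    sj <- if (j == 0L || j == n1) 0L else sg1[j]
    sl <- if (l == 0L || l == n2) 0L else sg2[l]
    if (!(sj == 0L || sl == 0L || (if (par) sj == sl else sj != sl))) next
    adjw <- adjw + pw[t] * pw[t + 1L]
    adjc <- adjc + 1L
  }
  c(adjw, sum(ew^2) + 2, adjc)
}

#' Exhaustive optimum of the family-free adjacency problem
#'
#' Enumerates every vertex-disjoint subset of the gene edges that covers all
#' gene components (the intermediate constraint), under both telomere
#' orientations, and returns a matching maximizing
#' `F_alpha = alpha * adj + (1 - alpha) * edg`. The problem is NP-hard, so
#' this is only feasible on small instances; it serves as the independent
#' verification oracle for the exact solver and the heuristic.
#'
#' Ties are broken deterministically: subsets are visited in lexicographic
#' order of the sorted edge list (include before exclude, parallel telomeres
#' before crossed) and the first optimum found is kept.
#'
#' @param graph an `ffadj_graph`.
#' @param alpha trade-off in `]0, 1]`.
#' @param max_edges refuse instances with more gene edges than this.
#' @return list with `matching` (an `ffadj_matching`) and `objective`
#'   (an `ffadj_objective`).
#' @export
brute_force_optimum <- function(graph, alpha, max_edges = 14L) {
  check_alpha(alpha)
  g <- graph
  m <- nrow(g$edges)
  if (m > max_edges) {
    stop("instance too large for brute force: ", m, " gene edges (limit ",
         max_edges, ")")
  }
  ei <- g$edges$i; ek <- g$edges$k; ew <- g$edges$w
  ecomp <- if (m > 0L) g$comp1[ei] else integer(0)
  n_comp <- g$n_comp
  best <- list(f = -Inf, sel = integer(0), crossed = FALSE)
  used1 <- logical(max(g$n1, 1L))
  used2 <- logical(max(g$n2, 1L))
  comp_cnt <- integer(max(n_comp, 1L))
  sel <- integer(0)

  leaf <- function() {
    if (n_comp > 0L && any(comp_cnt[seq_len(n_comp)] == 0L)) return()
    for (crossed in c(FALSE, TRUE)) {
      sc <- score_selection(g, ei[sel], ek[sel], ew[sel], crossed)
      f <- alpha * sc[1] + (1 - alpha) * sc[2]
      if (f > best$f + 1e-12) {
        best <<- list(f = f, sel = sel, crossed = crossed)
      }
    }
  }
  rec <- function(idx) {
    if (idx > m) { leaf(); return() }
    i <- ei[idx]; k <- ek[idx]
    if (!used1[i] && !used2[k]) {
      used1[i] <<- TRUE; used2[k] <<- TRUE
      comp_cnt[ecomp[idx]] <<- comp_cnt[ecomp[idx]] + 1L
      sel <<- c(sel, idx)
      rec(idx + 1L)
      sel <<- sel[-length(sel)]
      comp_cnt[ecomp[idx]] <<- comp_cnt[ecomp[idx]] - 1L
      used1[i] <<- FALSE; used2[k] <<- FALSE
    }
    rec(idx + 1L)
  }
  rec(1L)
  mm <- matching(g, g$edges[best$sel, c("i", "k"), drop = FALSE],
                 telomeres = if (best$crossed) "crossed" else "parallel")
  list(matching = mm, objective = f_alpha(mm, alpha))
}
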