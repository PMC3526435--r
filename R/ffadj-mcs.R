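# Greedy maximum-common-substring heuristic.
#
# The heuristic iterates three steps until no positive-similarity edge
# remains between unmatched genes: (1) enumerate maximal sign-consistent
# runs of similar gene pairs (in forward orientation, or reversed with
# opposite signs) among the still-unmatched genes, where "next" skips
# matched and deleted positions; (2) match the run with the best local
# alpha-weighted score; (3) delete hopeless genes (unmatched genes with no
# unmatched positive-similarity partner left) and try to extend previously
# matched runs across the freed flanks. Matched genes are never unmatched
# again.

new_heuristic_state <- function(graph) {
  g <- graph
  n1g <- g$n1 - 1L
  n2g <- g$n2 - 1L
  W <- matrix(0, nrow = max(n1g, 1L), ncol = max(n2g, 1L))
  if (nrow(g$edges)) W[cbind(g$edges$i, g$edges$k)] <- g$edges$w
  e <- new.env(parent = emptyenv())
  e$graph <- g
  e$W <- W
  e$st1 <- integer(n1g)   # 0 unmatched, 1 matched, 2 deleted
  e$st2 <- integer(n2g)
  e$partner1 <- integer(n1g)
  e$segments <- list()    # each: list(pairs = 2-col matrix, orientation)
  e
}

next_unm <- function(st, pos) {
  n <- length(st)
  p <- pos + 1L
  while (p <= n && st[p] != 0L) p <- p + 1L
  if (p <= n) p else NA_integer_
}
prev_unm <- function(st, pos) {
  p <- pos - 1L
  while (p >= 1L && st[p] != 0L) p <- p - 1L
  if (p >= 1L) p else NA_integer_
}

pair_valid <- function(state, i, k, orientation) {
  if (is.na(i) || is.na(k)) return(FALSE)
  if (state$st1[i] != 0L || state$st2[k] != 0L) return(FALSE)
  if (state$W[i, k] <= 0) return(FALSE)
  s1 <- state$graph$g1$signs[i]
  s2 <- state$graph$g2$signs[k]
  if (orientation == "forward") s1 == s2 else s1 == -s2
}

walk_run <- function(state, i, k, orientation) {
  pairs <- matrix(c(i, k), ncol = 2L)
  repeat {
    ni <- next_unm(state$st1, i)
    nk <- if (orientation == "forward") next_unm(state$st2, k)
          else prev_unm(state$st2, k)
    if (!pair_valid(state, ni, nk, orientation)) break
    pairs <- rbind(pairs, c(ni, nk))
    i <- ni; k <- nk
  }
  pairs
}

candidate_score <- function(state, pairs, alpha) {
  w <- state$W[pairs]
  alpha * sum(w[-length(w)] * w[-1L]) + (1 - alpha) * sum(w^2)
}

#' Enumerate common-substring candidates
#'
#' Lists every maximal run of unmatched, positive-similarity,
#' sign-consistent gene pairs, in forward orientation (equal signs,
#' both genomes ascending) and reversed orientation (opposite signs,
#' genome 2 descending). "Consecutive" skips matched and deleted positions.
#' Length-1 runs are admitted. Each candidate carries its local score
#' `alpha * sum of consecutive weight products + (1 - alpha) * sum of
#' squared weights`.
#'
#' @param state heuristic state from `new_heuristic_state()` (internal; see
#'   [run_heuristic()] for the user entry point).
#' @param alpha trade-off in `]0, 1]`.
#' @return list of candidates: `start1`, `start2`, `length`, `orientation`,
#'   `pairs` (2-column position matrix), `score`.
#' @keywords internal
enumerate_candidates <- function(state, alpha) {
  out <- list()
  n1g <- length(state$st1)
  n2g <- length(state$st2)
  for (orientation in c("forward", "reversed")) {
    for (i in seq_len(n1g)) {
      if (state$st1[i] != 0L) next
      for (k in seq_len(n2g)) {
        if (!pair_valid(state, i, k, orientation)) next
        pi <- prev_unm(state$st1, i)
        pk <- if (orientation == "forward") prev_unm(state$st2, k)
              else next_unm(state$st2, k)
        if (pair_valid(state, pi, pk, orientation)) next  # not maximal
        pairs <- walk_run(state, i, k, orientation)
        out[[length(out) + 1L]] <- list(
          start1 = i, start2 = k, length = nrow(pairs),
          orientation = orientation, pairs = pairs,
          score = candidate_score(state, pairs, alpha))
      }
    }
  }
  out
}

#' Select the maximum common substring
#'
#' Picks the candidate with maximal local score; ties are broken by the
#' smallest `(start1, start2)` with forward before reversed.
#'
#' @param candidates list from [enumerate_candidates()].
#' @param alpha unused (scores are precomputed); kept for symmetry.
#' @return one candidate.
#' @keywords internal
select_mcs <- function(candidates, alpha = NULL) {
  if (length(candidates) == 0L) stop("no candidates to select from")
  best <- candidates[[1L]]
  for (cand in candidates[-1L]) {
    if (cand$score > best$score + 1e-12) {
      best <- cand
    } else if (abs(cand$score - best$score) <= 1e-12) {
      a <- c(cand$start1, cand$start2, cand$orientation == "reversed")
      b <- c(best$start1, best$start2, best$orientation == "reversed")
      if (a[1] < b[1] || (a[1] == b[1] && a[2] < b[2]) ||
          (a[1] == b[1] && a[2] == b[2] && a[3] < b[3])) {
        best <- cand
      }
    }
  }
  best
}

match_candidate <- function(state, cand) {
  for (r in seq_len(nrow(cand$pairs))) {
    i <- cand$pairs[r, 1L]; k <- cand$pairs[r, 2L]
    stopifnot(state$st1[i] == 0L, state$st2[k] == 0L)
    state$st1[i] <- 1L
    state$st2[k] <- 1L
    state$partner1[i] <- k
  }
  state$segments[[length(state$segments) + 1L]] <-
    list(pairs = cand$pairs, orientation = cand$orientation)
  invisible(state)
}

#' Delete hopeless genes
#'
#' Removes every unmatched gene that has no positive-similarity unmatched
#' partner left in the other genome, re-checking to a fixed point.
#'
#' @param state heuristic state.
#' @return integer vector `c(genome1 deletions, genome2 deletions)`.
#' @keywords internal
delete_hopeless_genes <- function(state) {
  del <- c(0L, 0L)
  repeat {
    changed <- FALSE
    un2 <- which(state$st2 == 0L)
    for (i in which(state$st1 == 0L)) {
      if (length(un2) == 0L || all(state$W[i, un2] <= 0)) {
        state$st1[i] <- 2L
        del[1L] <- del[1L] + 1L
        changed <- TRUE
      }
    }
    un1 <- which(state$st1 == 0L)
    for (k in which(state$st2 == 0L)) {
      if (length(un1) == 0L || all(state$W[un1, k] <= 0)) {
        state$st2[k] <- 2L
        del[2L] <- del[2L] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  del
}

#' Extend matched segments over freed flanks
#'
#' For each previously matched run and each of its two extremities, the
#' nearest unmatched, undeleted genes flanking the run in both genomes are
#' matched and appended when they form a positive-similarity pair with the
#' run's orientation, repeating until blocked.
#'
#' @param state heuristic state.
#' @return number of gene pairs added.
#' @keywords internal
extend_segments <- function(state) {
  added <- 0L
  for (si in seq_along(state$segments)) {
    seg <- state$segments[[si]]
    fw <- seg$orientation == "forward"
    repeat {  # left extremity: smaller i side
      i0 <- seg$pairs[1L, 1L]; k0 <- seg$pairs[1L, 2L]
      pi <- prev_unm(state$st1, i0)
      pk <- if (fw) prev_unm(state$st2, k0) else next_unm(state$st2, k0)
      if (!pair_valid(state, pi, pk, seg$orientation)) break
      state$st1[pi] <- 1L; state$st2[pk] <- 1L
      state$partner1[pi] <- pk
      seg$pairs <- rbind(c(pi, pk), seg$pairs)
      added <- added + 1L
    }
    repeat {  # right extremity: larger i side
      nlast <- nrow(seg$pairs)
      i1 <- seg$pairs[nlast, 1L]; k1 <- seg$pairs[nlast, 2L]
      ni <- next_unm(state$st1, i1)
      nk <- if (fw) next_unm(state$st2, k1) else prev_unm(state$st2, k1)
      if (!pair_valid(state, ni, nk, seg$orientation)) break
      state$st1[ni] <- 1L; state$st2[nk] <- 1L
      state$partner1[ni] <- nk
      seg$pairs <- rbind(seg$pairs, c(ni, nk))
      added <- added + 1L
    }
    state$segments[[si]] <- seg
  }
  added
}

#' Greedy heuristic for the family-free adjacency problem
#'
#' Iteratively matches the common substring with the best local
#' alpha-weighted score (up to complete reversal), deletes hopeless genes
#' and extends earlier runs, stopping only when no positive-similarity edge
#' remains between unmatched genes. Because iteration continues to full
#' saturation, every component ends up with at least one matched edge, so
#' the result is a valid intermediate matching. Telomeres are pre-matched
#' parallel; if crossing them strictly improves the objective at the end,
#' they are flipped. The procedure is deterministic.
#'
#' @param graph an `ffadj_graph`.
#' @param alpha trade-off in `]0, 1]`.
#' @return list with `matching` (an `ffadj_matching`) and `objective`
#'   (an `ffadj_objective`).
#' @export
run_heuristic <- function(graph, alpha) {
  check_alpha(alpha)
  state <- new_heuristic_state(graph)
  repeat {
    cands <- enumerate_candidates(state, alpha)
    if (length(cands) == 0L) break
    match_candidate(state, select_mcs(cands))
    delete_hopeless_genes(state)
    extend_segments(state)
  }
  sel_i <- which(state$st1 == 1L)
  edges <- data.frame(i = sel_i, k = state$partner1[sel_i])
  m_par <- matching(graph, edges, telomeres = "parallel")
  m_cro <- matching(graph, edges, telomeres = "crossed")
  o_par <- f_alpha(m_par, alpha)
  o_cro <- f_alpha(m_cro, alpha)
  if (o_cro$f_alpha > o_par$f_alpha + 1e-12) {
    list(matching = m_cro, objective = o_cro)
  } else {
    list(matching = m_par, objective = o_par)
  }
}
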