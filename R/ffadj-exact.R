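#' Two-gene component preprocessing
#'
#' In an intermediate matching every component contributes an edge, so for a
#' component consisting of exactly two genes `G1[i]` and `G2[k]` the edge
#' `e_ik` must be in the matching. Fixing `a(i,k) = b1(i) = b2(k) = 1` in
#' turn fixes every consecutiveness variable spanning `i` (or `k`) and all
#' dependent adjacency variables to 0. This is the model's single
#' space-reduction rule.
#'
#' @param graph an `ffadj_graph`.
#' @return list with `forced_edges` (row indices into `graph$edges`),
#'   `i`, `k` (the fixed positions) and `c1_blocked`, `c2_blocked`
#'   (positions whose spanning consecutiveness variables are fixed to 0).
#' @export
preprocess_two_gene_components <- function(graph) {
  g <- graph
  forced <- integer(0)
  if (g$n_comp > 0L) {
    for (cid in seq_len(g$n_comp)) {
      c1 <- which(!is.na(g$comp1) & g$comp1 == cid)
      c2 <- which(!is.na(g$comp2) & g$comp2 == cid)
      if (length(c1) == 1L && length(c2) == 1L) {
        forced <- c(forced,
                    which(g$edges$i == c1 & g$edges$k == c2))
      }
    }
  }
  list(forced_edges = forced,
       i = g$edges$i[forced], k = g$edges$k[forced],
       c1_blocked = g$edges$i[forced], c2_blocked = g$edges$k[forced])
}

# sign screen for an adjacency variable: can the quadruple ever satisfy the
# orientation conditions given the fixed gene signs?
dvar_sign_ok <- function(g, i, j, k, l) {
  par <- k < l
  si <- sign_at(g$g1$signs, g$n1, i)
  sk <- sign_at(g$g2$signs, g$n2, k)
  sj <- sign_at(g$g1$signs, g$n1, j)
  sl <- sign_at(g$g2$signs, g$n2, l)
  ok1 <- si == 0L || sk == 0L || (if (par) si == sk else si != sk)
  ok2 <- sj == 0L || sl == 0L || (if (par) sj == sl else sj != sl)
  ok1 && ok2
}

#' Build the 0-1 linear program for the family-free adjacency problem
#'
#' Variables: `a(i,k)` select matching edges (defined only where the
#' similarity is positive, plus the four telomere edges), `b_x(i)` mark
#' saturated positions, `c_x(i,j)` mark consecutive pairs, and `d(i,j,k,l)`
#' mark conserved adjacencies. `d` variables are instantiated only for
#' quadruples whose fixed gene signs can satisfy the orientation conditions
#' (telomeres pass either condition) and where both underlying edges exist
#' with `i < j` and `k != l`.
#'
#' Constraints: each position saturated at most once (`sum_k a(i,k) = b1(i)`
#' and symmetrically); at least one saturated position per gene component
#' (the intermediate constraint); `c_x(i,j) + b_x(p) <= 1` for every
#' `i < p < j` (upper bounds only - an over-true `c` is harmless);
#' `d <= a(i,k)`, `d <= a(j,l)`, `d <= c1(i,j)`, `d <= c2(min(k,l),
#' max(k,l))`. The four telomere positions are fixed saturated and their
#' edges form exactly one parallel or crossed pair. The objective maximizes
#' `alpha * sum d * s(i,j,k,l) + (1 - alpha) * sum a * sigma^2` with
#' `s(i,j,k,l) = w(e_ik) * w(e_jl)`; telomere `a` variables carry weight
#' `(1 - alpha)` each.
#'
#' @param graph an `ffadj_graph`.
#' @param alpha trade-off in `]0, 1]`.
#' @return object of class `ffadj_ilp` with the variable tables, the
#'   preprocessing assignment (`fixed`) and bookkeeping used by
#'   [solve_exact()].
#' @export
build_ilp <- function(graph, alpha) {
  check_alpha(alpha)
  g <- graph
  # full edge list: gene edges then the four telomere edges
  m <- nrow(g$edges)
  ei <- c(g$edges$i, 0L, 0L, g$n1, g$n1)
  ek <- c(g$edges$k, 0L, g$n2, 0L, g$n2)
  ew <- c(g$edges$w, 1, 1, 1, 1)
  is_telo <- c(rep(FALSE, m), rep(TRUE, 4L))
  avars <- data.frame(i = ei, k = ek, w = ew, telomere = is_telo,
                      coef = (1 - alpha) * ew^2)
  # adjacency variables over ordered edge pairs
  dk <- new.env(hash = TRUE, parent = emptyenv())
  drows <- list()
  ne <- length(ei)
  for (a1 in seq_len(ne)) {
    for (a2 in seq_len(ne)) {
      i <- ei[a1]; j <- ei[a2]; k <- ek[a1]; l <- ek[a2]
      if (i >= j || k == l) next
      if (!dvar_sign_ok(g, i, j, k, l)) next
      s <- ew[a1] * ew[a2]
      key <- paste(i, j, k, l)
      assign(key, s, envir = dk)
      drows[[length(drows) + 1L]] <- c(i, j, k, l, s)
    }
  }
  dvars <- if (length(drows)) {
    dd <- as.data.frame(do.call(rbind, drows))
    names(dd) <- c("i", "j", "k", "l", "s")
    dd
  } else {
    data.frame(i = integer(), j = integer(), k = integer(),
               l = integer(), s = numeric())
  }
  comps <- connected_components(g)$components
  structure(list(graph = g, alpha = alpha, avars = avars, dvars = dvars,
                 dkey = dk, comps = comps,
                 fixed = preprocess_two_gene_components(g)),
            class = "ffadj_ilp")
}

#' @export
print.ffadj_ilp <- function(x, ...) {
  cat(sprintf(
    "<ffadj_ilp> alpha = %g: %d a-vars (%d telomeric), %d d-vars, %d components, %d fixed edges\n",
    x$alpha, nrow(x$avars), sum(x$avars$telomere), nrow(x$dvars),
    length(x$comps), length(x$fixed$forced_edges)))
  invisible(x)
}

#' Export the 0-1 program in LP text format
#'
#' Writes the model with explicit `a`, `b`, `c` and `d` variables and the
#' full constraint set in the standard LP file dialect, for inspection or
#' for feeding an external solver.
#'
#' @param model an `ffadj_ilp` from [build_ilp()].
#' @param path output path.
#' @export
write_lp <- function(model, path) {
  g <- model$graph
  av <- model$avars
  dv <- model$dvars
  an <- sprintf("a_%d_%d", av$i, av$k)
  dn <- if (nrow(dv)) sprintf("d_%d_%d_%d_%d", dv$i, dv$j, dv$k, dv$l)
        else character(0)
  obj <- c(sprintf("%.12g %s", av$coef, an),
           if (nrow(dv)) sprintf("%.12g %s", model$alpha * dv$s, dn))
  lines <- c("Maximize", paste(" obj:", paste(obj, collapse = " + ")),
             "Subject To")
  cons <- character(0)
  # C.01 via b: sum_k a(i,k) = b1(i), sum_i a(i,k) = b2(k)
  for (i in sort(unique(av$i))) {
    terms <- an[av$i == i]
    cons <- c(cons, sprintf(" c01_g1_%d: %s - b1_%d = 0", i,
                            paste(terms, collapse = " + "), i))
  }
  for (k in sort(unique(av$k))) {
    terms <- an[av$k == k]
    cons <- c(cons, sprintf(" c01_g2_%d: %s - b2_%d = 0", k,
                            paste(terms, collapse = " + "), k))
  }
  # C.02 intermediate constraint per gene component
  for (ci in seq_along(model$comps)) {
    cc <- model$comps[[ci]]
    terms <- c(sprintf("b1_%d", cc$c1), sprintf("b2_%d", cc$c2))
    cons <- c(cons, sprintf(" c02_%d: %s >= 1", ci,
                            paste(terms, collapse = " + ")))
  }
  # C.03 / C.04: c_x(i,j) + b_x(p) <= 1 for i < p < j, over positions that
  # occur in some d variable
  cpairs1 <- unique(dv[, c("i", "j"), drop = FALSE])
  if (nrow(cpairs1)) {
    for (r in seq_len(nrow(cpairs1))) {
      i <- cpairs1$i[r]; j <- cpairs1$j[r]
      for (p in seq_len(max(j - i - 1L, 0L)) + i) {
        if (p <= 0L || p >= g$n1) next
        cons <- c(cons, sprintf(" c03_%d_%d_%d: c1_%d_%d + b1_%d <= 1",
                                i, j, p, i, j, p))
      }
    }
  }
  cpairs2 <- if (nrow(dv)) unique(data.frame(k = pmin(dv$k, dv$l),
                                             l = pmax(dv$k, dv$l)))
             else data.frame()
  if (nrow(cpairs2)) {
    for (r in seq_len(nrow(cpairs2))) {
      k <- cpairs2$k[r]; l <- cpairs2$l[r]
      for (p in seq_len(max(l - k - 1L, 0L)) + k) {
        if (p <= 0L || p >= g$n2) next
        cons <- c(cons, sprintf(" c04_%d_%d_%d: c2_%d_%d + b2_%d <= 1",
                                k, l, p, k, l, p))
      }
    }
  }
  # C.05 / C.06: d below each of its factors
  if (nrow(dv)) {
    for (r in seq_len(nrow(dv))) {
      i <- dv$i[r]; j <- dv$j[r]; k <- dv$k[r]; l <- dv$l[r]
      nm <- dn[r]
      cons <- c(cons,
                sprintf(" c05a_%s: %s - a_%d_%d <= 0", nm, nm, i, k),
                sprintf(" c05b_%s: %s - a_%d_%d <= 0", nm, nm, j, l),
                sprintf(" c05c_%s: %s - c1_%d_%d <= 0", nm, nm, i, j),
                sprintf(" c06_%s: %s - c2_%d_%d <= 0", nm, nm,
                        min(k, l), max(k, l)))
    }
  }
  # telomere saturation and pairing
  cons <- c(cons,
            " telo_b1_0: b1_0 = 1",
            sprintf(" telo_b1_n: b1_%d = 1", g$n1),
            " telo_b2_0: b2_0 = 1",
            sprintf(" telo_b2_n: b2_%d = 1", g$n2))
  # fixed assignment from two-gene component preprocessing
  fx <- model$fixed
  if (length(fx$forced_edges)) {
    cons <- c(cons, sprintf(" fix_a_%d_%d: a_%d_%d = 1",
                            fx$i, fx$k, fx$i, fx$k))
  }
  bn <- c(sprintf("b1_%d", sort(unique(av$i))),
          sprintf("b2_%d", sort(unique(av$k))))
  cn <- unique(c(if (nrow(cpairs1)) sprintf("c1_%d_%d", cpairs1$i, cpairs1$j),
                 if (nrow(cpairs2)) sprintf("c2_%d_%d", cpairs2$k, cpairs2$l)))
  lines <- c(lines, cons, "Binary",
             paste("", paste(c(an, bn, cn, dn), collapse = " ")), "End")
  writeLines(lines, path)
  invisible(path)
}

#' Solve the family-free adjacency problem exactly
#'
#' Builds the 0-1 linear program of [build_ilp()] (applying the two-gene
#' component preprocessing) and solves it by depth-first branch-and-bound
#' over the `a` variables, one genome-1 position at a time. Given any full
#' `a` assignment the remaining variables are determined: `b` follows from
#' `a`; `c` takes its maximal feasible value (it only appears in upper
#' bounds); `d` has positive objective coefficient, so it is 1 exactly when
#' its four factor variables permit. Subtrees are pruned with an admissible
#' bound (each further edge can contribute at most two adjacency products
#' bounded by its weight, plus its squared weight) and when an uncovered
#' component has no selectable edge left.
#'
#' @param graph an `ffadj_graph`.
#' @param alpha trade-off in `]0, 1]`.
#' @param time_limit wall-clock budget in seconds; on expiry the best
#'   incumbent is returned flagged non-optimal.
#' @param model optionally a prebuilt `ffadj_ilp` (must match `graph` and
#'   `alpha`).
#' @return list with `matching`, `objective` (equal to
#'   `f_alpha(matching, alpha)` within 1e-6), `optimal` (logical
#'   optimality certificate) and `nodes` (search nodes visited).
#' @export
solve_exact <- function(graph, alpha, time_limit = 300, model = NULL) {
  check_alpha(alpha)
  g <- graph
  if (is.null(model)) model <- build_ilp(g, alpha)
  stopifnot(inherits(model, "ffadj_ilp"))
  m <- nrow(g$edges)
  n1 <- g$n1; n2 <- g$n2
  dk <- model$dkey
  # edges grouped by genome-1 position
  by_pos <- vector("list", max(n1 - 1L, 0L))
  if (m > 0L) {
    for (r in seq_len(m)) {
      i <- g$edges$i[r]
      by_pos[[i]] <- c(by_pos[[i]], r)
    }
  }
  forced_at <- integer(max(n1 - 1L, 0L))
  if (length(model$fixed$forced_edges)) {
    forced_at[g$edges$i[model$fixed$forced_edges]] <-
      model$fixed$forced_edges
  }
  # admissible potential per position and suffix sums
  pot_edge <- 2 * alpha * g$edges$w + (1 - alpha) * g$edges$w^2
  maxpot <- numeric(max(n1 - 1L, 0L))
  for (i in seq_len(n1 - 1L)) {
    if (length(by_pos[[i]])) maxpot[i] <- max(pot_edge[by_pos[[i]]])
  }
  suffpot <- rev(cumsum(rev(c(maxpot, 0))))
  const_ub <- (1 - alpha) * 2 + alpha  # telomere edges + telomere adjacency
  # component bookkeeping: last genome-1 position per component
  comp_last <- integer(max(g$n_comp, 1L))
  if (g$n_comp > 0L) {
    for (cid in seq_len(g$n_comp)) {
      comp_last[cid] <- max(which(!is.na(g$comp1) & g$comp1 == cid))
    }
  }
  ecomp <- if (m > 0L) g$comp1[g$edges$i] else integer(0)

  # leaf objective through the model's d-variable table
  leaf_obj <- function(sel) {
    sk <- g$edges$k[sel]
    sw <- g$edges$w[sel]
    base <- (1 - alpha) * (sum(sw^2) + 2)
    best_leaf <- -Inf
    best_cross <- FALSE
    for (crossed in c(FALSE, TRUE)) {
      s1 <- c(0L, g$edges$i[sel], n1)
      pk <- c(if (crossed) n2 else 0L, sk, if (crossed) 0L else n2)
      s2 <- sort(c(0L, sk, n2))
      rk <- match(pk, s2)
      acc <- 0
      for (t in seq_len(length(s1) - 1L)) {
        if (abs(rk[t] - rk[t + 1L]) != 1L) next
        key <- paste(s1[t], s1[t + 1L], pk[t], pk[t + 1L])
        s <- get0(key, envir = dk, ifnotfound = NULL)
        if (!is.null(s)) acc <- acc + s
      }
      f <- base + alpha * acc
      if (f > best_leaf + 1e-12) {
        best_leaf <- f
        best_cross <- crossed
      }
    }
    list(f = best_leaf, crossed = best_cross)
  }

  used2 <- logical(max(n2, 1L))
  comp_cnt <- integer(max(g$n_comp, 1L))
  sel <- integer(0)
  best <- list(f = -Inf, sel = integer(0), crossed = FALSE)
  nodes <- 0L
  t0 <- Sys.time()
  timed_out <- FALSE

  rec <- function(pos, sel_pot) {
    if (timed_out) return()
    nodes <<- nodes + 1L
    # honor the limit only once an incumbent exists, so a feasible (if
    # suboptimal) matching is always returned
    if (nodes %% 1024L == 0L && best$f > -Inf &&
        as.numeric(Sys.time() - t0, units = "secs") > time_limit) {
      timed_out <<- TRUE
      return()
    }
    if (pos >= n1) {
      if (g$n_comp > 0L && any(comp_cnt[seq_len(g$n_comp)] == 0L)) return()
      lo <- leaf_obj(sel)
      if (lo$f > best$f + 1e-12) {
        best <<- list(f = lo$f, sel = sel, crossed = lo$crossed)
      }
      return()
    }
    if (sel_pot + suffpot[pos] + const_ub <= best$f + 1e-12) return()
    # dead end check: components whose last selectable genome-1 position is
    # `pos` must be covered before moving past it
    dead_end <- function() {
      if (g$n_comp > 0L) {
        for (cid in which(comp_last == pos)) {
          if (comp_cnt[cid] == 0L) return(TRUE)
        }
      }
      FALSE
    }
    cand <- by_pos[[pos]]
    if (forced_at[pos] > 0L) cand <- forced_at[pos]
    for (r in cand) {
      k <- g$edges$k[r]
      if (used2[k]) next
      used2[k] <<- TRUE
      comp_cnt[ecomp[r]] <<- comp_cnt[ecomp[r]] + 1L
      sel <<- c(sel, r)
      if (!dead_end()) rec(pos + 1L, sel_pot + pot_edge[r])
      sel <<- sel[-length(sel)]
      comp_cnt[ecomp[r]] <<- comp_cnt[ecomp[r]] - 1L
      used2[k] <<- FALSE
    }
    if (forced_at[pos] == 0L && !dead_end()) rec(pos + 1L, sel_pot)
  }
  if (n1 <= 1L || m == 0L) {
    # no genes to branch over: telomere-only model
    lo <- leaf_obj(integer(0))
    best <- list(f = lo$f, sel = integer(0), crossed = lo$crossed)
  } else {
    rec(1L, 0)
  }
  if (best$f == -Inf) stop("0-1 program infeasible: model bug")
  mm <- matching(g, g$edges[best$sel, c("i", "k"), drop = FALSE],
                 telomeres = if (best$crossed) "crossed" else "parallel")
  obj <- f_alpha(mm, alpha)
  if (abs(obj$f_alpha - best$f) > 1e-6) {
    stop(sprintf(
      "decoded objective %.9f disagrees with solver objective %.9f: model bug",
      obj$f_alpha, best$f))
  }
  list(matching = mm, objective = obj, optimal = !timed_out, nodes = nodes)
}
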