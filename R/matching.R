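#' Construct a matching on a bipartite genome graph
#'
#' A matching is a set of pairwise vertex-disjoint gene-gene edges plus
#' exactly two telomere edges, either parallel (`e_{0,0}`, `e_{n1,n2}`) or
#' crossed (`e_{0,n2}`, `e_{n1,0}`). Telomere edges carry weight 1, are
#' counted in the matching size and participate in conserved adjacencies.
#'
#' @param graph an `ffadj_graph`.
#' @param edges data frame with columns `i`, `k` (pruned gene positions) or
#'   `i`, `k`, `w`; weights are looked up from the graph when absent.
#' @param telomeres `"parallel"` or `"crossed"`.
#' @return object of class `ffadj_matching`.
#' @export
matching <- function(graph, edges = data.frame(i = integer(), k = integer()),
                     telomeres = c("parallel", "crossed")) {
  stopifnot(inherits(graph, "ffadj_graph"))
  telomeres <- match.arg(telomeres)
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0L) {
    if (anyDuplicated(edges$i) || anyDuplicated(edges$k)) {
      stop("matching edges are not vertex-disjoint")
    }
    gk <- paste(graph$edges$i, graph$edges$k)
    hit <- match(paste(edges$i, edges$k), gk)
    if (anyNA(hit)) stop("matching contains edges absent from the graph")
    edges$w <- graph$edges$w[hit]
    edges <- edges[order(edges$i), c("i", "k", "w"), drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = integer(), k = integer(), w = numeric())
  }
  structure(list(graph = graph, edges = edges, telomeres = telomeres),
            class = "ffadj_matching")
}

#' @export
print.ffadj_matching <- function(x, ...) {
  cat(sprintf("<ffadj_matching> %d gene edges + 2 %s telomere edges\n",
              nrow(x$edges), x$telomeres))
  invisible(x)
}

# telomere partner of position 0 / n1 in G2 coordinates
telomere_partners <- function(m) {
  g <- m$graph
  if (m$telomeres == "parallel") c(`0` = 0L, n1 = g$n2)
  else c(`0` = g$n2, n1 = 0L)
}

# saturated positions (incl. telomeres) and partner/weight lookup
saturation_maps <- function(m) {
  g <- m$graph
  tp <- telomere_partners(m)
  s1 <- c(0L, m$edges$i, g$n1)
  p1 <- c(tp[[1]], m$edges$k, tp[[2]])
  w1 <- c(1, m$edges$w, 1)
  o <- order(s1)
  list(s1 = s1[o], p1 = p1[o], w1 = w1[o],
       s2 = sort(c(0L, m$edges$k, g$n2)))
}

sign_at <- function(genome_signs, n, pos) {
  if (pos == 0L || pos == n) 0L else genome_signs[pos]
}

# orientation compatibility: telomeres (sign 0) pass either condition
signs_compatible <- function(s1i, s2k, parallel_order) {
  if (s1i == 0L || s2k == 0L) return(TRUE)
  if (parallel_order) s1i == s2k else s1i != s2k
}

#' Consecutive pair test
#'
#' Positions `i < j` of one genome form a consecutive pair under a matching
#' iff no position strictly between them is saturated; unsaturated (or
#' pruned) genes in between do not break consecutiveness.
#'
#' @param m an `ffadj_matching`.
#' @param genome 1 or 2.
#' @param i,j positions with `i < j`.
#' @return logical.
#' @export
is_consecutive <- function(m, genome, i, j) {
  stopifnot(inherits(m, "ffadj_matching"), genome %in% c(1L, 2L))
  if (i >= j) stop("is_consecutive requires i < j")
  sat <- if (genome == 1L) c(0L, m$edges$i, m$graph$n1)
         else c(0L, m$edges$k, m$graph$n2)
  !any(sat > i & sat < j)
}

#' Conserved adjacency test
#'
#' Two matched pairs `(i, k)` and `(j, l)` form a conserved adjacency iff
#' both edges are in the matching, `(i, j)` and `(min(k,l), max(k,l))` are
#' consecutive pairs, and the orientations agree: for `k < l` the signs must
#' be pairwise equal, for `k > l` pairwise opposite; telomeres (sign 0)
#' satisfy either condition.
#'
#' @param m an `ffadj_matching`.
#' @param i,j positions in genome 1 with `i < j`; `k`, `l` their partners in
#'   genome 2 with `k != l`.
#' @return logical.
#' @export
is_conserved_adjacency <- function(m, i, j, k, l) {
  g <- m$graph
  if (!(i >= 0 && j <= g$n1 && i < j)) stop("require 0 <= i < j <= n1")
  if (!(k >= 0 && k <= g$n2 && l >= 0 && l <= g$n2)) {
    stop("require 0 <= k, l <= n2")
  }
  if (k == l) stop("require k != l")
  sm <- saturation_maps(m)
  pos_i <- match(i, sm$s1)
  pos_j <- match(j, sm$s1)
  if (is.na(pos_i) || is.na(pos_j)) return(FALSE)
  if (sm$p1[pos_i] != k || sm$p1[pos_j] != l) return(FALSE)
  if (!is_consecutive(m, 1L, i, j)) return(FALSE)
  if (!is_consecutive(m, 2L, min(k, l), max(k, l))) return(FALSE)
  par <- k < l
  signs_compatible(sign_at(g$g1$signs, g$n1, i),
                   sign_at(g$g2$signs, g$n2, k), par) &&
    signs_compatible(sign_at(g$g1$signs, g$n1, j),
                     sign_at(g$g2$signs, g$n2, l), par)
}

#' Score of one adjacency quadruple
#'
#' The product of the two edge weights when the quadruple is a conserved
#' adjacency under the matching, else 0.
#'
#' @inheritParams is_conserved_adjacency
#' @return numeric in `[0, 1]`.
#' @export
adjacency_score <- function(m, i, j, k, l) {
  if (!is_conserved_adjacency(m, i, j, k, l)) return(0)
  edge_weight(m$graph, i, k) * edge_weight(m$graph, j, l)
}

# core scorer: all conserved adjacencies of a matching in one scan.
# Only successive saturated positions of G1 can be consecutive pairs, so a
# single pass over the saturated order suffices.
conserved_adjacency_table <- function(m) {
  g <- m$graph
  sm <- saturation_maps(m)
  nsat <- length(sm$s1)
  res <- list()
  if (nsat >= 2L) {
    rank2 <- match(sm$p1, sm$s2)
    for (t in seq_len(nsat - 1L)) {
      i <- sm$s1[t]; j <- sm$s1[t + 1L]
      k <- sm$p1[t]; l <- sm$p1[t + 1L]
      # G2 consecutiveness: partners adjacent in the saturated order of G2
      if (abs(rank2[t] - rank2[t + 1L]) != 1L) next
      par <- k < l
      if (!signs_compatible(sign_at(g$g1$signs, g$n1, i),
                            sign_at(g$g2$signs, g$n2, k), par)) next
      if (!signs_compatible(sign_at(g$g1$signs, g$n1, j),
                            sign_at(g$g2$signs, g$n2, l), par)) next
      res[[length(res) + 1L]] <-
        c(i = i, j = j, k = k, l = l, score = sm$w1[t] * sm$w1[t + 1L])
    }
  }
  if (length(res) == 0L) {
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      l = integer(), score = numeric()))
  }
  as.data.frame(do.call(rbind, res))
}

#' Conserved adjacencies of a matching
#'
#' @param m an `ffadj_matching`.
#' @return data frame with one row per conserved adjacency: positions
#'   `i`, `j` (genome 1), `k`, `l` (genome 2) and the weight-product `score`.
#' @export
conserved_adjacencies <- function(m) {
  stopifnot(inherits(m, "ffadj_matching"))
  conserved_adjacency_table(m)
}

#' Weighted adjacency score adj(M)
#'
#' Sum of weight products over all conserved adjacencies (telomeric ones
#' included, with telomere edge weight 1).
#'
#' @param m an `ffadj_matching`.
#' @return numeric.
#' @export
adj_weight <- function(m) sum(conserved_adjacency_table(m)$score)

#' Weighted edge score edg(M)
#'
#' Sum of squared edge weights over the matching; the squares put edges on
#' the same scale as the adjacency products. The two telomere edges
#' contribute 1 each.
#'
#' @param m an `ffadj_matching`.
#' @return numeric.
#' @export
edg_weight <- function(m) sum(m$edges$w^2) + 2

#' Matching size and adjacency counts
#'
#' `edg_count` is the number of edges in the matching including the two
#' telomere edges; `adj_count` the number of conserved adjacencies including
#' telomeric ones.
#'
#' @param m an `ffadj_matching`.
#' @return integer.
#' @export
edg_count <- function(m) nrow(m$edges) + 2L

#' @rdname edg_count
#' @export
adj_count <- function(m) nrow(conserved_adjacency_table(m))

#' Combined objective F_alpha
#'
#' `F_alpha(M) = alpha * adj(M) + (1 - alpha) * edg(M)` for
#' `alpha` in `]0, 1]`.
#'
#' @param m an `ffadj_matching`.
#' @param alpha trade-off in `]0, 1]`; `alpha = 1` scores adjacencies only.
#' @return object of class `ffadj_objective`: list with `adj`, `edg`,
#'   `alpha`, `f_alpha`.
#' @export
f_alpha <- function(m, alpha) {
  check_alpha(alpha)
  a <- adj_weight(m)
  e <- edg_weight(m)
  structure(list(adj = a, edg = e, alpha = alpha,
                 f_alpha = alpha * a + (1 - alpha) * e),
            class = "ffadj_objective")
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("alpha must lie in ]0, 1]")
  }
  invisible(alpha)
}

#' @export
print.ffadj_objective <- function(x, ...) {
  cat(sprintf("F_%g = %.6f  (adj = %.6f, edg = %.6f)\n",
              x$alpha, x$f_alpha, x$adj, x$edg))
  invisible(x)
}

#' Intermediate-matching validity
#'
#' A matching is a valid intermediate matching iff its edges are pairwise
#' disjoint, the telomeres are matched as one parallel or crossed pair, and
#' every gene component of the graph contributes at least one edge.
#'
#' @param m an `ffadj_matching`.
#' @return logical.
#' @export
is_valid_intermediate <- function(m) {
  g <- m$graph
  if (anyDuplicated(m$edges$i) || anyDuplicated(m$edges$k)) return(FALSE)
  if (g$n_comp == 0L) return(TRUE)
  covered <- unique(g$comp1[m$edges$i])
  length(setdiff(seq_len(g$n_comp), covered)) == 0L
}

#' Breakpoint-like distance of a matching
#'
#' `Delta(M) = (#edg(M) - #adj(M) - 1) / #edg(M)` where `#edg` counts the
#' matching edges (telomere edges included) and `#adj` the conserved
#' adjacencies (telomeric ones included). For identical genomes under an
#' identity similarity the optimal matching attains `Delta = 0`. With
#' `weighted = TRUE` the weighted sums `edg(M)` / `adj(M)` replace the
#' counts; both variants coincide under unit weights.
#'
#' @param m an `ffadj_matching`.
#' @param weighted use weighted scores instead of counts.
#' @return numeric distance.
#' @export
delta_distance <- function(m, weighted = FALSE) {
  g <- m$graph
  if (g$n1 == 1L && g$n2 == 1L && nrow(m$edges) == 0L) {
    warning("degenerate genomes: all genes pruned; Delta = 0")
    return(0)
  }
  if (weighted) {
    e <- edg_weight(m)
    (e - adj_weight(m) - 1) / e
  } else {
    e <- edg_count(m)
    (e - adj_count(m) - 1) / e
  }
}

#' Write a matching as TSV
#'
#' One row per matched gene pair: the two gene ids, the edge weight and a
#' flag marking edges that take part in at least one conserved adjacency.
#' Telomere edges are recorded with id `"o"`.
#'
#' @param m an `ffadj_matching`.
#' @param path output path.
#' @export
write_matching <- function(m, path) {
  g <- m$graph
  ct <- conserved_adjacency_table(m)
  in_adj_i <- unique(c(ct$i, ct$j))
  tp <- telomere_partners(m)
  all_i <- c(0L, m$edges$i, g$n1)
  all_k <- c(tp[[1]], m$edges$k, tp[[2]])
  all_w <- c(1, m$edges$w, 1)
  id1 <- ifelse(all_i == 0L | all_i == g$n1, "o", g$g1$ids[pmax(all_i, 1L)])
  id2 <- ifelse(all_k == 0L | all_k == g$n2, "o", g$g2$ids[pmax(all_k, 1L)])
  df <- data.frame(gene_id_1 = id1, gene_id_2 = id2,
                   weight = all_w,
                   in_adjacency = as.integer(all_i %in% in_adj_i))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
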