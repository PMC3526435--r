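#' Build the ordered weighted bipartite graph between two genomes
#'
#' Vertices are the positions `0..n1` of `g1` and `0..n2` of `g2`. A gene
#' pair is connected iff its similarity is positive, with the similarity as
#' edge weight; the four telomere-telomere edges
#' (`e_{0,0}`, `e_{0,n2}`, `e_{n1,0}`, `e_{n1,n2}`) are always present with
#' weight 1, and gene-telomere edges never exist. Genes with no positive
#' similarity to any gene of the other genome ("unconnected" genes) are
#' removed from both gene orders before anything else; positions are
#' re-indexed while the original identifiers are retained, and the removed
#' ids are recorded on the result.
#'
#' @param g1,g2 `ffadj_genome` objects.
#' @param sim an `ffadj_similarity`; lookups are symmetric in the two ids.
#' @return object of class `ffadj_graph` with fields `g1`, `g2` (pruned
#'   genomes), `n1`, `n2` (sizes after pruning), `edges` (data frame
#'   `i`, `k`, `w` of gene-gene edges in pruned positions, sorted by
#'   `(i, k)`), `comp1`, `comp2` (connected-component label per gene
#'   position, telomere component excluded), `n_comp`, and `removed1`,
#'   `removed2` (pruned gene ids).
#' @export
build_graph <- function(g1, g2, sim) {
  stopifnot(inherits(g1, "ffadj_genome"), inherits(g2, "ffadj_genome"))
  known <- c(g1$ids, g2$ids)
  unknown <- setdiff(unique(c(sim$id1, sim$id2)), known)
  if (length(unknown)) {
    stop("similarity references unknown gene ids: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  # candidate gene-gene edges: sigma > 0 in either key orientation
  pick <- function(a_ids, b_ids) {
    i1 <- match(sim$id1, a_ids)
    k1 <- match(sim$id2, b_ids)
    ok <- !is.na(i1) & !is.na(k1)
    data.frame(i = i1[ok], k = k1[ok], w = sim$sigma[ok])
  }
  fwd <- pick(g1$ids, g2$ids)
  bwd <- pick(g2$ids, g1$ids)[, c(2, 1, 3)]
  names(bwd) <- c("i", "k", "w")
  ed <- rbind(fwd, bwd)
  if (nrow(ed) > 0L) {
    key <- paste(ed$i, ed$k)
    best <- tapply(ed$w, key, max)
    ed <- ed[!duplicated(key), , drop = FALSE]
    ed$w <- as.numeric(best[paste(ed$i, ed$k)])
  }
  # prune unconnected genes, re-index positions
  keep1 <- sort(unique(ed$i))
  keep2 <- sort(unique(ed$k))
  removed1 <- g1$ids[setdiff(seq_along(g1$ids), keep1)]
  removed2 <- g2$ids[setdiff(seq_along(g2$ids), keep2)]
  p1 <- if (length(keep1)) genome(g1$ids[keep1], g1$signs[keep1], g1$name)
        else structure(list(name = g1$name, ids = character(0),
                            signs = integer(0)), class = "ffadj_genome")
  p2 <- if (length(keep2)) genome(g2$ids[keep2], g2$signs[keep2], g2$name)
        else structure(list(name = g2$name, ids = character(0),
                            signs = integer(0)), class = "ffadj_genome")
  ed$i <- match(ed$i, keep1)
  ed$k <- match(ed$k, keep2)
  ed <- ed[order(ed$i, ed$k), , drop = FALSE]
  rownames(ed) <- NULL
  n1 <- length(p1$ids) + 1L
  n2 <- length(p2$ids) + 1L
  g <- structure(list(g1 = p1, g2 = p2, n1 = n1, n2 = n2, edges = ed,
                      comp1 = integer(max(n1 - 1L, 0L)),
                      comp2 = integer(max(n2 - 1L, 0L)),
                      n_comp = 0L,
                      removed1 = removed1, removed2 = removed2),
                 class = "ffadj_graph")
  compute_components(g)
}

# label gene connected components via igraph; vertices "A<i>" / "B<k>"
compute_components <- function(g) {
  m <- nrow(g$edges)
  if (m == 0L) {
    g$comp1 <- integer(0)
    g$comp2 <- integer(0)
    g$n_comp <- 0L
    return(g)
  }
  va <- paste0("A", g$edges$i)
  vb <- paste0("B", g$edges$k)
  ig <- igraph::graph_from_edgelist(cbind(va, vb), directed = FALSE)
  cc <- igraph::components(ig)$membership
  nm <- names(cc)
  g$comp1 <- rep(NA_integer_, g$n1 - 1L)
  g$comp2 <- rep(NA_integer_, g$n2 - 1L)
  a_idx <- startsWith(nm, "A")
  g$comp1[as.integer(substring(nm[a_idx], 2))] <- as.integer(cc[a_idx])
  g$comp2[as.integer(substring(nm[!a_idx], 2))] <- as.integer(cc[!a_idx])
  # relabel 1..n_comp in order of first appearance in G1
  labs <- unique(stats::na.omit(c(g$comp1, g$comp2)))
  g$comp1 <- match(g$comp1, labs)
  g$comp2 <- match(g$comp2, labs)
  g$n_comp <- length(labs)
  g
}

#' Connected components of the bipartite graph
#'
#' The four telomere edges always form a single component
#' `{0, n1} x {0, n2}`, reported separately under `telomere`; gene
#' components are listed with their vertex sets on both genomes.
#'
#' @param g an `ffadj_graph`.
#' @return list with `telomere` (list of the two telomere position pairs) and
#'   `components`: a list with one element per gene component holding `c1`
#'   and `c2`, the member positions in genome 1 and genome 2.
#' @export
connected_components <- function(g) {
  stopifnot(inherits(g, "ffadj_graph"))
  comps <- lapply(seq_len(g$n_comp), function(cid) {
    list(c1 = which(!is.na(g$comp1) & g$comp1 == cid),
         c2 = which(!is.na(g$comp2) & g$comp2 == cid))
  })
  list(telomere = list(g1 = c(0L, g$n1), g2 = c(0L, g$n2)),
       components = comps)
}

#' @export
print.ffadj_graph <- function(x, ...) {
  cat(sprintf(
    "<ffadj_graph> %s (size %d) vs %s (size %d): %d gene edges, %d gene components\n",
    x$g1$name, x$n1, x$g2$name, x$n2, nrow(x$edges), x$n_comp))
  if (length(x$removed1) || length(x$removed2)) {
    cat(sprintf("  pruned unconnected genes: %d from %s, %d from %s\n",
                length(x$removed1), x$g1$name,
                length(x$removed2), x$g2$name))
  }
  invisible(x)
}

#' Dump the graph edge list as TSV
#'
#' Writes one row per gene-gene edge: positions, gene ids and weight.
#' Intended for inspection; telomere edges are implicit.
#'
#' @param g an `ffadj_graph`.
#' @param path output path.
#' @export
write_graph_edges <- function(g, path) {
  df <- data.frame(pos_i = g$edges$i, pos_k = g$edges$k,
                   gene_id_i = g$g1$ids[g$edges$i],
                   gene_id_k = g$g2$ids[g$edges$k],
                   weight = g$edges$w)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# weight lookup for one edge (telomere edges weigh 1); 0 if absent
edge_weight <- function(g, i, k) {
  if ((i == 0L || i == g$n1) && (k == 0L || k == g$n2)) return(1)
  hit <- g$edges$w[g$edges$i == i & g$edges$k == k]
  if (length(hit)) hit[1] else 0
}
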