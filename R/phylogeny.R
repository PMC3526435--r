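#' All-pairs breakpoint-like distance matrix
#'
#' Computes the matching-derived distance `Delta` for every unordered pair
#' of genomes, using either the exact solver or the greedy heuristic.
#' Exact-solver failures (time limit reached without certificate) are
#' handled according to `fallback`: with `"heuristic"` the heuristic entry
#' is substituted, with `"na"` the entry is recorded as missing, leaving it
#' to the caller to subset taxa.
#'
#' @param genomes named list of `ffadj_genome` objects (at least 2).
#' @param sigmas either one `ffadj_similarity` covering all pairs (gene ids
#'   must be unique across genomes), or a named list keyed
#'   `"<name1>|<name2>"` (sorted names) with one similarity per pair.
#' @param alpha trade-off in `]0, 1]`.
#' @param method `"exact"` or `"heuristic"`.
#' @param fallback `"heuristic"` or `"na"`; only relevant for
#'   `method = "exact"`.
#' @param time_limit per-pair budget in seconds for the exact solver.
#' @return symmetric matrix of class `ffadj_distances` with zero diagonal
#'   and the genome names as dimnames; failed pairs are `NA`.
#' @export
pairwise_distance_matrix <- function(genomes, sigmas, alpha,
                                     method = c("exact", "heuristic"),
                                     fallback = c("heuristic", "na"),
                                     time_limit = 300) {
  method <- match.arg(method)
  fallback <- match.arg(fallback)
  check_alpha(alpha)
  stopifnot(length(genomes) >= 2L)
  nms <- names(genomes)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("genomes must be a uniquely named list")
  }
  sigma_for <- function(a, b) {
    if (inherits(sigmas, "ffadj_similarity")) {
      # one table for all pairs: keep only rows between these two genomes
      ids <- c(genomes[[a]]$ids, genomes[[b]]$ids)
      sub <- sigmas[sigmas$id1 %in% ids & sigmas$id2 %in% ids, ,
                    drop = FALSE]
      class(sub) <- c("ffadj_similarity", "data.frame")
      return(sub)
    }
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!key %in% names(sigmas)) stop("missing similarities for pair ", key)
    sigmas[[key]]
  }
  n <- length(genomes)
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      g <- build_graph(genomes[[a]], genomes[[b]], sigma_for(nms[a], nms[b]))
      d <- if (method == "heuristic") {
        delta_distance(run_heuristic(g, alpha)$matching)
      } else {
        res <- solve_exact(g, alpha, time_limit = time_limit)
        if (res$optimal) {
          delta_distance(res$matching)
        } else if (fallback == "heuristic") {
          delta_distance(run_heuristic(g, alpha)$matching)
        } else {
          NA_real_
        }
      }
      D[a, b] <- D[b, a] <- d
    }
  }
  class(D) <- c("ffadj_distances", "matrix", "array")
  D
}

#' Neighbor joining tree reconstruction
#'
#' Standard Saitou-Nei agglomeration implemented in-package: at each step
#' the pair minimizing the Q criterion is joined, with ties broken
#' deterministically by the lowest index pair in the current matrix order.
#' Negative branch lengths are clamped to 0 with a warning.
#'
#' @param D symmetric distance matrix with dimnames (>= 3 taxa, no `NA`).
#' @return an unrooted `phylo` tree (ape format) with branch lengths.
#' @export
neighbor_joining <- function(D) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) < 3L) stop("neighbor joining needs >= 3 taxa")
  if (anyNA(D)) {
    stop("incomplete distance matrix: impute or subset taxa first")
  }
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix not symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  fmt <- function(x) sprintf("%.12g", x)
  # each active cluster carries a growing newick fragment
  nwk <- labels
  while (nrow(D) > 3L) {
    N <- nrow(D)
    r <- rowSums(D)
    qbest <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(N - 1L)) {
      for (j in seq(i + 1L, N)) {
        q <- (N - 2) * D[i, j] - r[i] - r[j]
        if (q < qbest - 1e-12) {
          qbest <- q; bi <- i; bj <- j
        }
      }
    }
    li <- bl(D[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (N - 2)))
    lj <- bl(D[bi, bj] - (D[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (N - 2))))
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[bi], fmt(li), nwk[bj], fmt(lj))
    du <- (D[bi, ] + D[bj, ] - D[bi, bj]) / 2
    keep <- setdiff(seq_len(N), c(bi, bj))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  lx <- bl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  ly <- bl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lz <- bl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  if (clamped) warning("negative branch length(s) clamped to 0")
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(lx),
                 nwk[2], fmt(ly), nwk[3], fmt(lz))
  ape::read.tree(text = txt)
}

# non-trivial bipartitions of an unrooted tree as canonical strings
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  tips <- sort(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  # edges in postorder so children are resolved before parents
  eo <- ape::reorder.phylo(tree, "postorder")
  for (r in seq_len(nrow(eo$edge))) {
    p <- eo$edge[r, 1L]; ch <- eo$edge[r, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  out <- character(0)
  for (r in seq_len(nrow(eo$edge))) {
    ch <- eo$edge[r, 2L]
    if (ch <= n) next  # trivial split (single tip)
    side <- sort(desc[[ch]])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (tips[1L] %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(side, collapse = "\r"))
  }
  unique(out)
}

#' Robinson-Foulds topological distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees (symmetric difference). Trees must share an identical
#' leaf set; they are unrooted before comparison. Two binary trees that
#' differ by a single internal edge (one NNI) have distance 2.
#'
#' @param t1,t2 `phylo` trees.
#' @return integer distance.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label)
  l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) stop("trees have different leaf sets")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Newick input and output
#'
#' Thin wrappers around the ape tree parser/serializer; round-trips
#' preserve topology and branch lengths.
#'
#' @param path file path.
#' @return `read_newick`: a `phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in ", path)
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a square PHYLIP distance matrix
#'
#' Standard square format: the taxon count on the first line, then one row
#' per taxon with the name truncated/padded to 10 characters.
#'
#' @param D symmetric numeric matrix with dimnames, zero diagonal.
#' @param path output path.
#' @export
write_phylip_distances <- function(D, path) {
  D <- unclass(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (anyNA(D)) stop("distance matrix contains missing entries")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix not symmetric")
  nms <- rownames(D)
  if (is.null(nms)) nms <- paste0("t", seq_len(nrow(D)))
  nms <- formatC(substr(nms, 1L, 10L), width = 10L, flag = "-")
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste0(nms[i], paste(sprintf("%.6f", D[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path file in the format written by [write_phylip_distances()].
#' @return symmetric numeric matrix with taxon names as dimnames.
#' @export
read_phylip_distances <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  nms <- character(n)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ln <- lines[i + 1L]
    nms[i] <- trimws(substr(ln, 1L, 10L))
    D[i, ] <- as.numeric(strsplit(trimws(substring(ln, 11L)),
                                  "[ \t]+")[[1L]])
  }
  dimnames(D) <- list(nms, nms)
  D
}

#' Write distances as a NEXUS block
#'
#' For downstream split-network tools; emits a `taxa` and a `distances`
#' block with the full square matrix.
#'
#' @param D symmetric numeric matrix with dimnames.
#' @param path output path.
#' @export
write_nexus_distances <- function(D, path) {
  D <- unclass(D)
  nms <- rownames(D)
  n <- nrow(D)
  lines <- c("#NEXUS", "", "BEGIN taxa;",
             sprintf("    DIMENSIONS ntax=%d;", n), "    TAXLABELS",
             sprintf("        %s", nms), "    ;", "END;", "",
             "BEGIN distances;",
             sprintf("    DIMENSIONS ntax=%d;", n),
             "    FORMAT triangle=both diagonal labels;",
             "    MATRIX",
             vapply(seq_len(n), function(i) {
               paste0("        ", nms[i], " ",
                      paste(sprintf("%.6f", D[i, ]), collapse = " "))
             }, character(1)),
             "    ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
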