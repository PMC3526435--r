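#' Simulation configuration
#'
#' Parameters of the seeded gene-order simulator. A simulated gene order
#' evolves from a common ancestor by inversions (a random interval is
#' reversed and its signs negated), duplications (a random gene is copied
#' to a random position; every further duplication generation decays the
#' similarity to its family multiplicatively) and losses (a random gene is
#' deleted). The similarity matrix is generated directly, standing in for a
#' sequence-derived measure: true homolog pairs receive a high weight with
#' mild jitter, duplicated copies receive geometrically decayed weights,
#' and a Poisson number of spurious low-weight edges is sprinkled between
#' non-homologs.
#'
#' @param n_genes ancestor gene count (>= 2).
#' @param n_inversions,n_duplications,n_losses event counts per branch.
#' @param sigma_true mean similarity of surviving true homolog pairs,
#'   in `(0, 1]`.
#' @param sigma_decay multiplicative similarity factor per duplication
#'   generation, in `(0, 1]`.
#' @param noise_edges expected number of spurious similarity edges.
#' @param noise_weight_max upper bound of spurious weights; keep below
#'   `sigma_true` so noise stays below true-pair weights.
#' @param seed integer seed; the whole instance replays deterministically.
#' @return list of class `ffadj_sim_config`.
#' @export
simulation_config <- function(n_genes = 10L, n_inversions = 2L,
                              n_duplications = 1L, n_losses = 1L,
                              sigma_true = 0.9, sigma_decay = 0.7,
                              noise_edges = 2, noise_weight_max = 0.3,
                              seed = 1L) {
  if (n_genes < 2L) stop("invalid config: n_genes must be >= 2")
  if (min(n_inversions, n_duplications, n_losses) < 0L) {
    stop("invalid config: negative event count")
  }
  if (sigma_true <= 0 || sigma_true > 1) {
    stop("invalid config: sigma_true outside (0, 1]")
  }
  if (sigma_decay <= 0 || sigma_decay > 1) {
    stop("invalid config: sigma_decay outside (0, 1]")
  }
  if (noise_weight_max < 0 || noise_weight_max >= 1) {
    stop("invalid config: noise_weight_max outside [0, 1)")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_inversions = as.integer(n_inversions),
                 n_duplications = as.integer(n_duplications),
                 n_losses = as.integer(n_losses),
                 sigma_true = sigma_true, sigma_decay = sigma_decay,
                 noise_edges = noise_edges,
                 noise_weight_max = noise_weight_max,
                 seed = as.integer(seed)),
            class = "ffadj_sim_config")
}

# internal gene-state representation during evolution: data frame with
# origin (ancestor index), dup_depth, sign
ancestor_state <- function(n_genes) {
  data.frame(origin = seq_len(n_genes),
             dup_depth = 0L,
             sign = sample(c(-1L, 1L), n_genes, replace = TRUE))
}

# applies inversions, then duplications, then losses; records an event log
evolve_branch <- function(genes, n_inversions, n_duplications, n_losses) {
  log <- list()
  for (e in seq_len(n_inversions)) {
    n <- nrow(genes)
    if (n < 1L) break
    ends <- sort(sample.int(n, 2L, replace = TRUE))
    seg <- seq(ends[1L], ends[2L])
    inv <- genes[rev(seg), , drop = FALSE]
    inv$sign <- -inv$sign
    genes[seg, ] <- inv
    log[[length(log) + 1L]] <- list(op = "inversion", from = ends[1L],
                                    to = ends[2L])
  }
  for (e in seq_len(n_duplications)) {
    n <- nrow(genes)
    if (n < 1L) break
    src <- sample.int(n, 1L)
    at <- sample.int(n + 1L, 1L)
    copy <- genes[src, , drop = FALSE]
    copy$dup_depth <- copy$dup_depth + 1L
    head_ <- if (at > 1L) genes[seq_len(at - 1L), , drop = FALSE]
    tail_ <- if (at <= n) genes[seq(at, n), , drop = FALSE]
    genes <- rbind(head_, copy, tail_)
    rownames(genes) <- NULL
    log[[length(log) + 1L]] <- list(op = "duplication", source = src,
                                    at = at)
  }
  for (e in seq_len(n_losses)) {
    n <- nrow(genes)
    if (n < 2L) break
    at <- sample.int(n, 1L)
    genes <- genes[-at, , drop = FALSE]
    log[[length(log) + 1L]] <- list(op = "loss", at = at)
  }
  rownames(genes) <- NULL
  list(genes = genes, log = log)
}

state_to_genome <- function(genes, prefix, name) {
  counts <- stats::ave(genes$origin, genes$origin, FUN = seq_along)
  ids <- ifelse(genes$dup_depth == 0L & counts == 1L,
                sprintf("%s%d", prefix, genes$origin),
                sprintf("%s%d.c%d", prefix, genes$origin, counts))
  genome(ids, genes$sign, name = name)
}

# similarity rows between two evolved gene states; true pairs share an
# origin, weight sigma_true decayed per duplication generation with mild
# multiplicative jitter
homology_sigma <- function(st1, ids1, st2, ids2, config) {
  rows <- list()
  for (a in seq_len(nrow(st1))) {
    hits <- which(st2$origin == st1$origin[a])
    for (b in hits) {
      depth <- st1$dup_depth[a] + st2$dup_depth[b]
      w <- config$sigma_true * config$sigma_decay^depth *
        stats::runif(1L, 0.95, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        id1 = ids1[a], id2 = ids2[b], sigma = min(w, 1))
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(id1 = character(), id2 = character(), sigma = numeric())
}

noise_sigma <- function(st1, ids1, st2, ids2, config) {
  nn <- stats::rpois(1L, config$noise_edges)
  rows <- list()
  if (nn > 0L && nrow(st1) > 0L && nrow(st2) > 0L &&
      config$noise_weight_max > 0) {
    for (e in seq_len(nn)) {
      a <- sample.int(nrow(st1), 1L)
      b <- sample.int(nrow(st2), 1L)
      if (st1$origin[a] == st2$origin[b]) next  # keep noise non-homologous
      w <- stats::runif(1L, 1e-6, config$noise_weight_max)
      rows[[length(rows) + 1L]] <- data.frame(
        id1 = ids1[a], id2 = ids2[b], sigma = w)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(id1 = character(), id2 = character(), sigma = numeric())
}

#' Simulate a related genome pair with planted matching
#'
#' The first genome is the ancestor itself; the second is the ancestor
#' evolved by the configured inversions, duplications and losses. The
#' similarity matrix connects genes sharing an ancestral origin (decayed
#' per duplication generation, jittered) plus spurious noise edges. The
#' planted matching pairs each ancestor gene with its least-duplicated
#' surviving copy; if noise edges create components without any planted
#' edge, the heaviest edge of such a component is added so the planted
#' matching is always a valid intermediate matching.
#'
#' @param config an `ffadj_sim_config`.
#' @return list of class `ffadj_instance`: `g1`, `g2`, `sigma`, `graph`,
#'   `planted` (an `ffadj_matching`), `event_log`, `config`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "ffadj_sim_config"))
  set.seed(config$seed)
  anc <- ancestor_state(config$n_genes)
  ev <- evolve_branch(anc, config$n_inversions, config$n_duplications,
                      config$n_losses)
  st1 <- anc
  st2 <- ev$genes
  g1 <- state_to_genome(st1, "a", "G1")
  g2 <- state_to_genome(st2, "b", "G2")
  sig_rows <- rbind(homology_sigma(st1, g1$ids, st2, g2$ids, config),
                    noise_sigma(st1, g1$ids, st2, g2$ids, config))
  sigma <- similarity_matrix(sig_rows$id1, sig_rows$id2, sig_rows$sigma)
  graph <- build_graph(g1, g2, sigma)
  planted <- planted_edges(graph, st1, g1, st2, g2)
  inst <- structure(list(g1 = g1, g2 = g2, sigma = sigma, graph = graph,
                         planted = planted, event_log = ev$log,
                         config = config),
                    class = "ffadj_instance")
  inst
}

# planted matching: ancestor gene -> least-duplicated surviving copy,
# completed with the heaviest edge of any uncovered component
planted_edges <- function(graph, st1, g1, st2, g2) {
  id_pairs <- list()
  pos1 <- match(g1$ids, graph$g1$ids)
  pos2 <- match(g2$ids, graph$g2$ids)
  used2 <- rep(FALSE, length(g2$ids))
  for (a in seq_along(g1$ids)) {
    if (is.na(pos1[a])) next  # pruned
    hits <- which(st2$origin == st1$origin[a] & !used2 & !is.na(pos2))
    if (length(hits) == 0L) next
    b <- hits[order(st2$dup_depth[hits], hits)][1L]
    used2[b] <- TRUE
    id_pairs[[length(id_pairs) + 1L]] <- c(pos1[a], pos2[b])
  }
  ed <- if (length(id_pairs)) {
    as.data.frame(do.call(rbind, id_pairs))
  } else {
    data.frame(V1 = integer(), V2 = integer())
  }
  names(ed) <- c("i", "k")
  # drop planted pairs whose edge is absent (can happen only if sigma rounds
  # to zero, which the generator never does) and complete coverage
  gk <- paste(graph$edges$i, graph$edges$k)
  ed <- ed[paste(ed$i, ed$k) %in% gk, , drop = FALSE]
  if (graph$n_comp > 0L) {
    covered <- unique(graph$comp1[ed$i])
    for (cid in setdiff(seq_len(graph$n_comp), covered)) {
      cand <- which(graph$comp1[graph$edges$i] == cid &
                      !(graph$edges$i %in% ed$i) &
                      !(graph$edges$k %in% ed$k))
      if (length(cand)) {
        r <- cand[order(-graph$edges$w[cand], cand)][1L]
        ed <- rbind(ed, data.frame(i = graph$edges$i[r],
                                   k = graph$edges$k[r]))
      }
    }
  }
  matching(graph, ed)
}

#' @export
print.ffadj_instance <- function(x, ...) {
  cat(sprintf(
    "<ffadj_instance> seed %d: %d + %d genes, %d sigma entries, %d planted edges\n",
    x$config$seed, length(x$g1$ids), length(x$g2$ids), nrow(x$sigma),
    nrow(x$planted$edges)))
  invisible(x)
}

#' Write a simulated instance to files
#'
#' Emits the gene-order TSV, the similarity TSV, the planted matching TSV
#' and a flat key-value config file into a directory, in the same formats
#' the readers consume.
#'
#' @param instance an `ffadj_instance`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_instance <- function(instance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_orders(list(instance$g1, instance$g2),
                    file.path(dir, "genomes.tsv"))
  write_similarities(instance$sigma, file.path(dir, "similarities.tsv"))
  write_matching(instance$planted, file.path(dir, "planted.tsv"))
  cfg <- instance$config
  writeLines(paste0(names(cfg), "=", unlist(cfg)),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Simulate gene orders along a phylogeny
#'
#' Evolves an ancestral gene order along every branch of a binary guide
#' tree, applying the per-branch event counts of `config` independently on
#' each edge. Leaf genomes are returned together with pairwise similarity
#' matrices (shared ancestral origin, decayed per accumulated duplication
#' generation, plus noise) and the generating topology as ground truth.
#'
#' @param tree a `phylo` object or Newick string with >= 4 leaves.
#' @param config an `ffadj_sim_config`; `n_genes` sizes the ancestor and
#'   the event counts apply per branch.
#' @return list with `genomes` (named list), `sigmas` (named list keyed
#'   `"<name1>|<name2>"` with sorted names) and `tree` (the guide tree).
#' @export
simulate_tree_dataset <- function(tree, config) {
  stopifnot(inherits(config, "ffadj_sim_config"))
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (length(tree$tip.label) < 4L) stop("invalid tree: need >= 4 leaves")
  set.seed(config$seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- ancestor_state(config$n_genes)
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (r in seq_len(nrow(eo$edge))) {
    p <- eo$edge[r, 1L]; ch <- eo$edge[r, 2L]
    states[[ch]] <- evolve_branch(states[[p]], config$n_inversions,
                                  config$n_duplications,
                                  config$n_losses)$genes
  }
  genomes <- list()
  for (t in seq_len(n_tip)) {
    nm <- tree$tip.label[t]
    genomes[[nm]] <- state_to_genome(states[[t]], paste0(nm, "_"), nm)
  }
  sigmas <- list()
  nms <- tree$tip.label
  for (a in seq_len(n_tip - 1L)) {
    for (b in seq(a + 1L, n_tip)) {
      sa <- states[[a]]; sb <- states[[b]]
      rows <- rbind(
        homology_sigma(sa, genomes[[nms[a]]]$ids, sb,
                       genomes[[nms[b]]]$ids, config),
        noise_sigma(sa, genomes[[nms[a]]]$ids, sb,
                    genomes[[nms[b]]]$ids, config))
      key <- paste(sort(c(nms[a], nms[b])), collapse = "|")
      sigmas[[key]] <- similarity_matrix(rows$id1, rows$id2, rows$sigma)
    }
  }
  list(genomes = genomes, sigmas = sigmas, tree = tree)
}
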