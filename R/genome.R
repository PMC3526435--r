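#' Construct a signed gene order
#'
#' A genome is modelled as a single linear chromosome: an ordered sequence of
#' signed genes flanked by two unsigned telomeres. Positions are numbered
#' `0..n` where positions `0` and `n` hold the telomeres and positions
#' `1..n-1` hold the genes; a genome with `n - 1` genes has size `n`.
#'
#' @param ids character vector of gene identifiers, in chromosomal order.
#'   Identifiers must be unique within a genome.
#' @param signs integer (or numeric) vector of strand signs, `+1` or `-1`,
#'   one per gene.
#' @param name genome label.
#' @return An object of class `ffadj_genome` with fields `name`, `ids` and
#'   `signs`. Telomeres are implicit at positions `0` and `n`.
#' @examples
#' g <- genome(c("dnaA", "gyrB", "recA"), c(1, 1, -1), name = "toy")
#' genome_size(g)  # 4: three genes plus one, by the size convention
#' @export
genome <- function(ids, signs, name = "genome") {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("empty genome: no genes supplied")
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id within genome '", name, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  signs <- as.integer(signs)
  if (length(signs) != length(ids)) stop("ids and signs differ in length")
  if (!all(signs %in% c(-1L, 1L))) stop("gene signs must be +1 or -1")
  structure(list(name = as.character(name), ids = ids, signs = signs),
            class = "ffadj_genome")
}

#' Genome size
#'
#' By convention a genome holding `n - 1` genes has size `n` (the index of its
#' trailing telomere).
#'
#' @param g an `ffadj_genome`.
#' @return integer size `n`.
#' @export
genome_size <- function(g) {
  stopifnot(inherits(g, "ffadj_genome"))
  length(g$ids) + 1L
}

#' @export
print.ffadj_genome <- function(x, ...) {
  n <- genome_size(x)
  shown <- paste0(ifelse(x$signs < 0, "-", ""), x$ids)
  if (length(shown) > 8) shown <- c(shown[1:8], "...")
  cat(sprintf("<ffadj_genome> %s: %d genes (size %d)\n", x$name, n - 1L, n))
  cat("  (o, ", paste(shown, collapse = ", "), ", o)\n", sep = "")
  invisible(x)
}

#' Orientation of a gene
#'
#' Returns `+1` for a forward gene, `-1` for a reverse gene and `0` for a
#' telomere. Telomeres (sign 0) are compatible with either orientation when
#' adjacency sign conditions are tested.
#'
#' @param g an `ffadj_genome`.
#' @param pos position in `0..n`; `0` and `n` are the telomeres.
#' @return integer in `{-1, 0, 1}`.
#' @export
gene_sign <- function(g, pos) {
  n <- genome_size(g)
  if (any(pos < 0L | pos > n)) stop("position out of range 0..", n)
  ifelse(pos == 0L | pos == n, 0L, g$signs[pmax(pos, 1L)])
}

parse_sign_token <- function(tok) {
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("+", "+1", "1")] <- 1L
  out[tok %in% c("-", "-1")] <- -1L
  if (anyNA(out)) {
    stop("malformed sign token(s): ",
         paste(unique(tok[is.na(out)]), collapse = ", "),
         " (expected '+' or '-')")
  }
  out
}

#' Read gene orders from a tab-separated table
#'
#' The table has four columns: `genome_name`, `rank`, `gene_id`, `sign`
#' (`+`/`-`). One file may hold several genomes; within each genome the rows
#' are sorted by `rank` to give the chromosomal order. A genome name occurring
#' with non-contiguous duplicated ranks is rejected.
#'
#' @param path path to the TSV file (a header line is optional and detected).
#' @return named list of [genome()] objects, one per `genome_name`.
#' @export
read_gene_orders <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "#", blank.lines.skip = TRUE),
    error = function(e) data.frame())
  if (nrow(tab) == 0L) stop("empty genome: no records in ", path)
  if (ncol(tab) < 4L) stop("gene-order table needs 4 columns: ",
                           "genome_name, rank, gene_id, sign")
  if (identical(tolower(tab[1, 1]), "genome_name")) tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0L) stop("empty genome: no records in ", path)
  names(tab)[1:4] <- c("genome_name", "rank", "gene_id", "sign")
  rank <- suppressWarnings(as.numeric(tab$rank))
  if (anyNA(rank)) stop("non-numeric rank in gene-order table")
  out <- list()
  for (nm in unique(tab$genome_name)) {
    rows <- tab[tab$genome_name == nm, , drop = FALSE]
    o <- order(rank[tab$genome_name == nm])
    rows <- rows[o, , drop = FALSE]
    out[[nm]] <- genome(rows$gene_id, parse_sign_token(rows$sign), name = nm)
  }
  out
}

#' Read a single genome from a gene-order table
#'
#' @param path path to a gene-order TSV (see [read_gene_orders()]).
#' @param name genome name to extract; may be omitted when the file holds
#'   exactly one genome. Files holding several genomes without a `name`
#'   argument are rejected (one linear chromosome per genome).
#' @return an `ffadj_genome`.
#' @export
read_genome <- function(path, name = NULL) {
  gs <- read_gene_orders(path)
  if (is.null(name)) {
    if (length(gs) != 1L) {
      stop("file holds ", length(gs), " genomes; a genome is a single ",
           "linear chromosome - pass `name` to select one")
    }
    return(gs[[1L]])
  }
  if (!name %in% names(gs)) stop("genome '", name, "' not found in ", path)
  gs[[name]]
}

#' Write gene orders to a tab-separated table
#'
#' Inverse of [read_gene_orders()]; round-trips order, identifiers and signs
#' exactly.
#'
#' @param genomes a single `ffadj_genome` or a list of them.
#' @param path output file path.
#' @export
write_gene_orders <- function(genomes, path) {
  if (inherits(genomes, "ffadj_genome")) genomes <- list(genomes)
  rows <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(genome_name = g$name, rank = seq_along(g$ids),
               gene_id = g$ids, sign = ifelse(g$signs < 0, "-", "+"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Linearize a circular gene order
#'
#' Rotates a circular chromosome so that the gene at `origin` (0-based offset
#' into the circular order) comes first, then flanks the result with
#' telomeres. Whatever origin is chosen, the number of conserved adjacencies
#' of an optimal matching against a fixed partner changes by at most one,
#' since only the single adjacency spanning the chosen breakage point can be
#' lost.
#'
#' @param ids,signs circular gene order (vectors as in [genome()]).
#' @param origin 0-based rotation offset; gene `origin + 1` becomes the first
#'   gene of the linearized chromosome. Default 0 keeps the stored order.
#' @param name genome label.
#' @return an `ffadj_genome`.
#' @export
linearize_circular <- function(ids, signs, origin = 0L, name = "genome") {
  m <- length(ids)
  if (m == 0L) stop("empty genome: no genes supplied")
  origin <- as.integer(origin)
  if (origin < 0L || origin >= m) stop("origin out of range 0..", m - 1L)
  idx <- c(seq_len(m)[-seq_len(origin)], seq_len(origin))
  if (origin == 0L) idx <- seq_len(m)
  genome(ids[idx], signs[idx], name = name)
}
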