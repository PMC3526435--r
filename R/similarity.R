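#' Construct a sparse gene similarity matrix
#'
#' Holds a normalized similarity measure sigma between genes of two genomes
#' as a sparse table of pairs with weight in (0, 1]. Absent pairs mean
#' sigma = 0. Pairs given with sigma <= 0 are dropped; sigma > 1 is rejected.
#'
#' @param id1,id2 character vectors of gene identifiers.
#' @param sigma numeric weights.
#' @return object of class `ffadj_similarity`: a data frame with columns
#'   `id1`, `id2`, `sigma`, duplicated pairs collapsed to their maximum.
#' @export
similarity_matrix <- function(id1 = character(), id2 = character(),
                              sigma = numeric()) {
  sigma <- as.numeric(sigma)
  if (anyNA(sigma)) stop("non-numeric similarity value")
  if (any(sigma > 1 + 1e-12)) stop("similarity not normalized: sigma > 1")
  keep <- sigma > 0
  df <- data.frame(id1 = as.character(id1)[keep],
                   id2 = as.character(id2)[keep],
                   sigma = pmin(sigma[keep], 1),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    key <- paste(df$id1, df$id2, sep = "\r")
    df <- df[order(key), , drop = FALSE]
    key <- sort(key)
    grp <- !duplicated(key)
    df$sigma <- vapply(split(df$sigma, cumsum(grp)), max, numeric(1))[
      cumsum(grp)]
    df <- df[grp, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("ffadj_similarity", "data.frame")
  df
}

#' Read a similarity TSV
#'
#' Expects three columns `gene_id_1`, `gene_id_2`, `sigma` (header optional).
#' Rows with sigma <= 0 are dropped (sigma = 0 means no edge); sigma > 1 is
#' an error.
#'
#' @param path TSV file path.
#' @return an `ffadj_similarity`.
#' @export
read_similarities <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "#", blank.lines.skip = TRUE),
    error = function(e) data.frame())
  if (nrow(tab) == 0L) return(similarity_matrix())
  if (ncol(tab) < 3L) stop("similarity table needs 3 columns")
  if (identical(tolower(tab[1, 1]), "gene_id_1")) tab <- tab[-1, , drop = FALSE]
  sig <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(sig)) stop("non-numeric similarity value in ", path)
  similarity_matrix(tab[[1]], tab[[2]], sig)
}

#' Write a similarity TSV
#'
#' @param sim an `ffadj_similarity`.
#' @param path output path.
#' @export
write_similarities <- function(sim, path) {
  utils::write.table(as.data.frame(sim)[, c("id1", "id2", "sigma")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Look up similarity values for gene pairs
#'
#' The lookup is symmetric in the two identifiers: a pair stored as
#' `(a, x)` is found for the query `(x, a)` as well.
#'
#' @param sim an `ffadj_similarity`.
#' @param a,b character vectors of gene ids (recycled to common length).
#' @return numeric vector of sigma values, 0 where the pair is absent.
#' @export
similarity_of <- function(sim, a, b) {
  k1 <- paste(a, b, sep = "\r")
  k2 <- paste(b, a, sep = "\r")
  key <- paste(sim$id1, sim$id2, sep = "\r")
  v <- sim$sigma[match(k1, key)]
  v2 <- sim$sigma[match(k2, key)]
  v[is.na(v)] <- v2[is.na(v)]
  v[is.na(v)] <- 0
  v
}

#' Read BLAST tabular output
#'
#' Reads 12-column tabular alignment output (outfmt-6 style) and keeps the
#' columns query id, subject id and bit score. Duplicate (query, subject)
#' rows are collapsed to the maximum bit score.
#'
#' @param path BLAST tabular file.
#' @return data frame with columns `query`, `subject`, `bitscore`.
#' @export
read_blast_tabular <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "#", blank.lines.skip = TRUE),
    error = function(e) data.frame())
  if (nrow(tab) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  if (ncol(tab) < 3L) stop("BLAST tabular output needs >= 3 columns")
  bs_col <- if (ncol(tab) >= 12L) 12L else ncol(tab)
  bs <- suppressWarnings(as.numeric(tab[[bs_col]]))
  if (anyNA(bs)) stop("non-numeric bit score in ", path)
  if (any(bs < 0)) stop("negative bit score in ", path)
  df <- data.frame(query = tab[[1]], subject = tab[[2]], bitscore = bs,
                   stringsAsFactors = FALSE)
  key <- paste(df$query, df$subject, sep = "\r")
  best <- tapply(df$bitscore, key, max)
  df <- df[!duplicated(key), , drop = FALSE]
  df$bitscore <- as.numeric(best[paste(df$query, df$subject, sep = "\r")])
  rownames(df) <- NULL
  df
}

best_hit_lookup <- function(hits) {
  v <- hits$bitscore
  names(v) <- paste(hits$query, hits$subject, sep = "\r")
  v
}

#' Relative reciprocal BLAST score similarity
#'
#' Builds the normalized similarity sigma between the genes of two genomes
#' from BLAST bit scores:
#' `sigma(g1, g2) = (bs(g1->g2) + bs(g2->g1)) / (bs(g1->g1) + bs(g2->g2))`.
#' A pair lacking a hit in either direction gets sigma = 0 (reciprocity is
#' required); values are clamped to at most 1. A gene with cross hits but no
#' self hit, or a zero self score, is an error.
#'
#' @param hits_ab hits of genome A queried against genome B
#'   (as from [read_blast_tabular()]).
#' @param hits_ba hits of genome B against genome A.
#' @param self_a,self_b self-comparison tables providing each gene's self-hit
#'   bit score.
#' @return an `ffadj_similarity` keyed (gene of A, gene of B).
#' @export
rrbs_from_blast <- function(hits_ab, hits_ba, self_a, self_b) {
  self_score <- function(self_tab) {
    own <- self_tab[self_tab$query == self_tab$subject, , drop = FALSE]
    v <- own$bitscore
    names(v) <- own$query
    if (any(v <= 0)) {
      stop("zero self-score for gene(s): ",
           paste(own$query[v <= 0], collapse = ", "))
    }
    v
  }
  sa <- self_score(self_a)
  sb <- self_score(self_b)
  if (nrow(hits_ab) == 0L && nrow(hits_ba) == 0L) {
    return(similarity_matrix())
  }
  fwd <- best_hit_lookup(hits_ab)
  rev_ <- best_hit_lookup(hits_ba)
  # reciprocal pairs only: (a, b) needs both a->b and b->a
  pairs <- data.frame(a = hits_ab$query, b = hits_ab$subject,
                      stringsAsFactors = FALSE)
  bs_ba <- rev_[paste(pairs$b, pairs$a, sep = "\r")]
  keep <- !is.na(bs_ba)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) return(similarity_matrix())
  bs_ab <- fwd[paste(pairs$a, pairs$b, sep = "\r")]
  bs_ba <- bs_ba[keep]
  miss_a <- setdiff(pairs$a, names(sa))
  miss_b <- setdiff(pairs$b, names(sb))
  if (length(miss_a) || length(miss_b)) {
    stop("missing self-hit for gene(s): ",
         paste(c(miss_a, miss_b), collapse = ", "))
  }
  sigma <- (bs_ab + bs_ba) / (sa[pairs$a] + sb[pairs$b])
  similarity_matrix(pairs$a, pairs$b, pmin(sigma, 1))
}
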