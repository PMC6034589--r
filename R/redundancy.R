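# Alignment-free k-tuple distances and the iterative exclusion of highly
# similar epitopes.
#
# The distance between two peptides is one minus the fraction of shared
# length-k words (as a multiset), normalised by the number of words in the
# shorter sequence. Epitope sets are pruned until every remaining pairwise
# distance exceeds a threshold (default 0.5, i.e. ~50% difference for
# equal-length peptides at k = 1), removing at each step the member of the
# closest pair that sits deepest inside the retained set.

.tuples <- function(s, k) {
  n <- nchar(s)
  if (n < k) stop("sequence shorter than k", call. = FALSE)
  substring(s, 1:(n - k + 1), k:n)
}

#' k-tuple distance between two sequences
#'
#' `1 - |multiset intersection of k-tuples| / (min(len(a), len(b)) - k + 1)`;
#' 0 for identical sequences, 1 when no k-tuple is shared.
#'
#' @param a,b amino-acid sequences.
#' @param k word length (default 1).
#' @return a real in `[0, 1]`.
#' @examples
#' ktuple_distance("AAAAA", "AAACC", k = 1)  # 0.4
#' @export
ktuple_distance <- function(a, b, k = 1L) {
  if (k < 1) stop("k must be a positive integer", call. = FALSE)
  if (min(nchar(a), nchar(b)) < k) {
    stop("k exceeds the length of the shorter sequence", call. = FALSE)
  }
  ta <- table(.tuples(a, k))
  tb <- table(.tuples(b, k))
  shared <- intersect(names(ta), names(tb))
  inter <- sum(pmin(as.integer(ta[shared]), as.integer(tb[shared])))
  1 - inter / (min(nchar(a), nchar(b)) - k + 1)
}

#' Pairwise k-tuple distance matrix
#'
#' @param seqs character vector of sequences; names (if present) become the
#'   matrix labels and must be unique.
#' @param k word length (default 1).
#' @return symmetric numeric matrix with zero diagonal and entries in
#'   `[0, 1]`.
#' @export
distance_matrix <- function(seqs, k = 1L) {
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  if (min(nchar(seqs)) < k) {
    stop("k exceeds the length of the shortest sequence", call. = FALSE)
  }
  n <- length(seqs)
  tup <- lapply(seqs, .tuples, k = k)
  vocab <- unique(unlist(tup, use.names = FALSE))
  counts <- matrix(0L, n, length(vocab))
  for (i in seq_len(n)) {
    tb <- table(factor(tup[[i]], levels = vocab))
    counts[i, ] <- as.integer(tb)
  }
  inter <- matrix(0, n, n)
  for (t in seq_along(vocab)) {
    v <- counts[, t]
    inter <- inter + pmin(matrix(v, n, n), matrix(v, n, n, byrow = TRUE))
  }
  denom <- nchar(seqs) - k + 1
  dmat <- 1 - inter / pmin(matrix(denom, n, n), matrix(denom, n, n, byrow = TRUE))
  diag(dmat) <- 0
  dimnames(dmat) <- list(ids, ids)
  dmat
}

#' Iteratively remove highly similar sequences
#'
#' In each iteration the pair (or pairs) attaining the smallest pairwise
#' distance is identified; within each such pair, the member with the smaller
#' mean distance to all other currently retained peptides is excluded (ties
#' broken by removing the later input sequence). Iterations repeat until
#' every remaining pairwise distance is strictly greater than `threshold`.
#'
#' The default word length is `k = 2` (dipeptides): identical and
#' frame-shifted overlapping peptides share most of their dipeptides and fall
#' well below the 0.5 threshold, while unrelated peptides sit near 1. At
#' `k = 1` the bag-of-residues overlap between even unrelated 15-mers over
#' the 20-letter alphabet is so large that no sizeable mutually-distant set
#' exists.
#'
#' @param seqs character vector of sequences (optionally named by id).
#' @param threshold distance threshold in `(0, 1)`; default 0.5.
#' @param k word length for the k-tuple distance (default 2).
#' @return the kept sequences, a subset of `seqs` preserving input order.
#' @export
filter_redundant <- function(seqs, threshold = 0.5, k = 2L) {
  stopifnot(threshold > 0, threshold < 1)
  if (length(seqs) == 0) return(seqs)
  if (length(seqs) == 1) return(seqs)
  dmat <- distance_matrix(seqs, k = k)
  n <- length(seqs)
  retained <- rep(TRUE, n)
  repeat {
    idx <- which(retained)
    if (length(idx) < 2) break
    sub <- dmat[idx, idx, drop = FALSE]
    offdiag <- sub[upper.tri(sub)]
    m <- min(offdiag)
    if (m > threshold) break
    hits <- which(upper.tri(sub) & sub <= m + 1e-12, arr.ind = TRUE)
    # global indices of minimal pairs, processed in deterministic order
    pairs <- cbind(idx[hits[, 1]], idx[hits[, 2]])
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    removed_now <- integer(0)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      if (i %in% removed_now || j %in% removed_now) next
      mean_i <- mean(dmat[i, setdiff(idx, i)])
      mean_j <- mean(dmat[j, setdiff(idx, j)])
      drop <- if (mean_i < mean_j) i
              else if (mean_j < mean_i) j
              else max(i, j)
      retained[drop] <- FALSE
      removed_now <- c(removed_now, drop)
    }
  }
  seqs[retained]
}
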