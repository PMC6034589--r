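# 5-mer proteome-similarity machinery.
#
# Short peptide words (5-mers by default) act as units of immunological
# recognition: an epitope set whose 5-mers occur often in the human proteome
# is "human-like", one dominated by proteome-absent 5-mers is foreign.
# This file provides overlapping k-mer decomposition, occurrence counting
# against a proteome, rarity profiles (fraction of epitope 5-mers found a
# given number of times in the proteome) and the label-permutation test that
# compares the rare/common 5-mer content of two epitope sets.

#' Decompose a sequence into overlapping k-mers
#'
#' Duplicated k-mers are retained: every occurrence counts in the downstream
#' tallies.
#'
#' @param sequence a single amino-acid sequence with `nchar >= k`.
#' @param k word length (default 5).
#' @return character vector of the `nchar - k + 1` overlapping windows, in
#'   order.
#' @export
decompose_kmers <- function(sequence, k = 5L) {
  stopifnot(length(sequence) == 1L)
  if (nchar(sequence) < k) {
    stop("sequence shorter than k = ", k, call. = FALSE)
  }
  .tuples(sequence, k)
}

# k-mers containing the unknown residue X are excluded from all tallies:
# they cannot be meaningfully matched against the proteome.
.drop_x <- function(kmers) kmers[!grepl("X", kmers, fixed = TRUE)]

#' Build a k-mer occurrence index of a proteome
#'
#' Counts every overlapping k-mer of every protein; occurrences never span
#' two proteins. k-mers containing `X` are skipped.
#'
#' @param proteome character vector of protein sequences, or a `data.frame`
#'   with a `sequence` column as returned by [read_fasta()].
#' @param k word length (default 5).
#' @param proteome_id label carried along for provenance.
#' @return an object of class `kmer_occurrence_table` whose `counts` element
#'   maps every k-mer present in the proteome to its occurrence count; k-mers
#'   absent from `counts` occur zero times.
#' @export
kmer_occurrence_index <- function(proteome, k = 5L, proteome_id = "proteome") {
  if (is.data.frame(proteome)) proteome <- proteome$sequence
  stopifnot(length(proteome) >= 1)
  long <- proteome[nchar(proteome) >= k]
  words <- .drop_x(unlist(lapply(long, .tuples, k = k), use.names = FALSE))
  counts <- if (length(words)) table(words) else integer(0)
  structure(list(k = as.integer(k),
                 counts = setNames(as.integer(counts), names(counts)),
                 proteome_id = proteome_id,
                 complete = TRUE),
            class = "kmer_occurrence_table")
}

#' Count proteome occurrences of query k-mers
#'
#' @param kmers character vector of query k-mers (all of length `k`).
#' @param proteome proteome sequences (or `read_fasta()` output), or a
#'   prebuilt [kmer_occurrence_index()].
#' @param k word length; inferred from an index argument.
#' @param proteome_id provenance label.
#' @return a `kmer_occurrence_table` whose `counts` cover exactly the unique
#'   query k-mers (0 for k-mers absent from the proteome).
#' @examples
#' count_occurrences("AAAAA", "AAAAAA")$counts  # 2 overlapping occurrences
#' @export
count_occurrences <- function(kmers, proteome, k = 5L,
                              proteome_id = "proteome") {
  if (inherits(proteome, "kmer_occurrence_table")) {
    index <- proteome
    k <- index$k
  } else {
    index <- kmer_occurrence_index(proteome, k = k, proteome_id = proteome_id)
  }
  kmers <- unique(kmers)
  if (any(nchar(kmers) != k)) {
    stop("all query k-mers must have length k = ", k, call. = FALSE)
  }
  hit <- index$counts[kmers]
  counts <- ifelse(is.na(hit), 0L, hit)
  structure(list(k = k,
                 counts = setNames(as.integer(counts), kmers),
                 proteome_id = index$proteome_id,
                 complete = FALSE),
            class = "kmer_occurrence_table")
}

#' @export
print.kmer_occurrence_table <- function(x, ...) {
  cat("k-mer occurrence table (k = ", x$k, ", ", length(x$counts),
      " k-mers, proteome ", x$proteome_id, ")\n", sep = "")
  invisible(x)
}

# per-epitope qualifying/total k-mer counts; the workhorse behind profiles
# and the permutation test
.epitope_kmer_counts <- function(epitopes, occ) {
  k <- occ$k
  kmer_list <- lapply(epitopes, function(e) .drop_x(decompose_kmers(e, k)))
  all_kmers <- unlist(kmer_list, use.names = FALSE)
  idx <- match(all_kmers, names(occ$counts))
  if (anyNA(idx)) {
    if (occ$complete) {
      cnt_all <- ifelse(is.na(idx), 0L, occ$counts[idx])
    } else {
      stop("occurrence table does not cover 5-mer ",
           all_kmers[which(is.na(idx))[1]], call. = FALSE)
    }
  } else {
    cnt_all <- occ$counts[idx]
  }
  list(counts = as.integer(cnt_all),
       epitope = rep(seq_along(epitopes), lengths(kmer_list)),
       totals = lengths(kmer_list))
}

#' Rarity profile of an epitope set
#'
#' For every occurrence count `c`, the fraction of epitope k-mers (with
#' multiplicity) found exactly `c` times in the proteome.
#'
#' @param epitopes character vector of epitope sequences.
#' @param occurrence_table a [count_occurrences()] result covering every
#'   k-mer of every epitope (or a complete [kmer_occurrence_index()]).
#' @return an object of class `rarity_profile` with elements
#'   `per_occurrence` (named fractions, names are occurrence counts),
#'   `n_kmers` and `k`.
#' @export
rarity_profile <- function(epitopes, occurrence_table) {
  stopifnot(inherits(occurrence_table, "kmer_occurrence_table"),
            length(epitopes) >= 1)
  ek <- .epitope_kmer_counts(epitopes, occurrence_table)
  if (!length(ek$counts)) stop("no countable k-mers in the epitope set",
                               call. = FALSE)
  tab <- table(ek$counts)
  per <- as.numeric(tab) / length(ek$counts)
  structure(list(per_occurrence = setNames(per, names(tab)),
                 n_kmers = length(ek$counts),
                 k = occurrence_table$k),
            class = "rarity_profile")
}

#' @export
print.rarity_profile <- function(x, ...) {
  cat("rarity profile over ", x$n_kmers, " ", x$k, "-mers\n", sep = "")
  print(round(x$per_occurrence, 4))
  invisible(x)
}

#' Fraction of rare (or common) k-mers in a profile
#'
#' @param profile a [rarity_profile()].
#' @param cutoff occurrence-count cutoff (inclusive).
#' @param mode `"rare"` counts k-mers occurring `<= cutoff` times,
#'   `"common"` counts those occurring `>= cutoff` times.
#' @return a fraction in `[0, 1]`.
#' @export
rare_fraction <- function(profile, cutoff, mode = c("rare", "common")) {
  mode <- match.arg(mode)
  if (cutoff < 0) stop("cutoff must be non-negative", call. = FALSE)
  occ <- as.numeric(names(profile$per_occurrence))
  keep <- if (mode == "rare") occ <= cutoff else occ >= cutoff
  sum(profile$per_occurrence[keep])
}

#' Label-permutation test of rare/common k-mer content
#'
#' Tests whether the DQ-associated epitope set differs from the DR-associated
#' set in its fraction of rare (occurrence `<= cutoff`) or common
#' (occurrence `>= cutoff`) proteome k-mers. Epitopes are pooled and randomly
#' reassigned to the two groups (preserving set sizes) `n_iter` times; the
#' p-value is the probability of a difference at least as large as the
#' observed one arising by chance.
#'
#' The observed difference is signed so that it is positive when the DQ set
#' is the more human-like one: `rare(DR) - rare(DQ)` in rare mode and
#' `common(DQ) - common(DR)` in common mode.
#'
#' @param set_dq,set_dr character vectors of epitope sequences.
#' @param occurrence_table occurrence counts covering both sets (a complete
#'   [kmer_occurrence_index()] also works).
#' @param cutoff occurrence cutoff defining rare/common.
#' @param mode `"rare"` or `"common"`.
#' @param n_iter number of random label assignments (default 10000).
#' @param seed integer seed; the test is fully reproducible from it.
#' @param alternative `"magnitude"` (default) counts permutations whose
#'   absolute difference reaches the observed absolute difference;
#'   `"observed"` is one-sided in the direction of the observed difference;
#'   `"greater"` is one-sided in the fixed hypothesised direction (DQ more
#'   human-like).
#' @return an object of class `permutation_test_result` with the observed
#'   difference, the null differences, the p-value, the per-set fractions and
#'   the statistic specification.
#' @export
permutation_test <- function(set_dq, set_dr, occurrence_table, cutoff = 0,
                             mode = c("rare", "common"), n_iter = 10000L,
                             seed = 1L,
                             alternative = c("magnitude", "observed",
                                             "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  stopifnot(length(set_dq) >= 1, length(set_dr) >= 1)
  if (n_iter < 1) stop("n_iter must be at least 1", call. = FALSE)
  ek <- .epitope_kmer_counts(c(set_dq, set_dr), occurrence_table)
  qual <- if (mode == "rare") ek$counts <= cutoff else ek$counts >= cutoff
  # per-epitope counts of qualifying and total k-mers
  n_epi <- length(set_dq) + length(set_dr)
  q <- numeric(n_epi)
  agg <- rowsum(as.numeric(qual), group = ek$epitope, reorder = TRUE)
  q[as.integer(rownames(agg))] <- agg[, 1]
  t <- as.numeric(ek$totals)
  n_dq <- length(set_dq)
  Q <- sum(q); Tt <- sum(t)
  sq_obs <- sum(q[seq_len(n_dq)]); st_obs <- sum(t[seq_len(n_dq)])
  f_dq <- sq_obs / st_obs
  f_dr <- (Q - sq_obs) / (Tt - st_obs)
  observed <- if (mode == "rare") f_dr - f_dq else f_dq - f_dr
  null_diffs <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      grp <- sample.int(n_epi, n_dq)
      sq <- sum(q[grp]); st <- sum(t[grp])
      f1 <- sq / st; f2 <- (Q - sq) / (Tt - st)
      if (mode == "rare") f2 - f1 else f1 - f2
    }, 0)
  })
  eps <- 1e-12
  p <- switch(alternative,
    magnitude = mean(abs(null_diffs) >= abs(observed) - eps),
    greater = mean(null_diffs >= observed - eps),
    observed = if (observed > 0) mean(null_diffs >= observed - eps)
               else if (observed < 0) mean(null_diffs <= observed + eps)
               else 1)
  structure(list(observed_diff = observed,
                 null_diffs = null_diffs,
                 p_value = p,
                 fractions = c(dq = f_dq, dr = f_dr),
                 statistic_spec = list(cutoff = cutoff, mode = mode),
                 alternative = alternative,
                 n_iter = n_iter,
                 seed = seed),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  spec <- x$statistic_spec
  cat(sprintf("permutation test (%s 5-mers, cutoff %s, %d iterations)\n",
              spec$mode, spec$cutoff, x$n_iter))
  cat(sprintf("  fraction DQ: %.4f  fraction DR: %.4f  diff: %+.4f\n",
              x$fractions["dq"], x$fractions["dr"], x$observed_diff))
  if (x$p_value == 0) {
    cat(sprintf("  p < %g (no permutation reached the observed difference)\n",
                1 / x$n_iter))
  } else {
    cat(sprintf("  p = %g (%s)\n", x$p_value, x$alternative))
  }
  invisible(x)
}
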