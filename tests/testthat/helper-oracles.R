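# Independent reference implementations used as oracles. These are written
# naively (direct loops over definitions) and deliberately share no code with
# the package internals they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_peptides <- function(n, len = 15) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, len, replace = TRUE), collapse = "")
  }, "")
}

# multiset k-tuple distance, by explicit per-word counting
naive_ktuple <- function(a, b, k) {
  words <- function(s) {
    vapply(seq_len(nchar(s) - k + 1), function(i) substr(s, i, i + k - 1), "")
  }
  wa <- words(a); wb <- words(b)
  inter <- 0
  remaining <- wb
  for (w in wa) {
    hit <- match(w, remaining)
    if (!is.na(hit)) {
      inter <- inter + 1
      remaining <- remaining[-hit]
    }
  }
  1 - inter / (min(nchar(a), nchar(b)) - k + 1)
}

# the iterative exclusion loop, recomputed from scratch every iteration
naive_filter <- function(seqs, threshold = 0.5, k = 2) {
  keep <- seq_along(seqs)
  repeat {
    if (length(keep) < 2) break
    n <- length(keep)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- naive_ktuple(seqs[keep[i]], seqs[keep[j]], k)
    }
    off <- d[upper.tri(d)]
    m <- min(off)
    if (m > threshold) break
    removed <- integer(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (d[i, j] <= m + 1e-12) {
        gi <- keep[i]; gj <- keep[j]
        if (gi %in% removed || gj %in% removed) next
        mi <- mean(d[i, -i]); mj <- mean(d[j, -j])
        drop <- if (mi < mj) gi else if (mj < mi) gj else max(gi, gj)
        removed <- c(removed, drop)
      }
    }
    keep <- setdiff(keep, removed)
  }
  seqs[keep]
}

# overlapping substring occurrences by explicit position scan
naive_count <- function(kmer, proteins) {
  k <- nchar(kmer)
  total <- 0
  for (p in proteins) {
    if (nchar(p) < k) next
    for (i in seq_len(nchar(p) - k + 1)) {
      if (substr(p, i, i + k - 1) == kmer) total <- total + 1
    }
  }
  total
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
# tables with the observed margins
fisher_p_enum <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kcol <- sum(tab[, 1])
  lo <- max(0, kcol - n); hi <- min(kcol, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, kcol)
  d_obs <- dhyper(a, m, n, kcol)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

# step-up BH from the definition
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# --- fixed-rank predictor: returns preset rank percentiles ------------------
# ranks: named list allele -> either a single rank (applied to every
# sequence) or a named numeric vector (per sequence)
fixed_rank_predictor <- function(ranks) {
  structure(list(ranks = ranks), class = "fixed_rank_predictor")
}

predict_rank.fixed_rank_predictor <- function(predictor, sequence, allele,
                                              ...) {
  if (!allele %in% names(predictor$ranks)) {
    stop("unknown allele: ", allele, call. = FALSE)
  }
  r <- predictor$ranks[[allele]]
  if (length(r) == 1L && is.null(names(r))) return(rep(r, length(sequence)))
  out <- unname(r[sequence])
  if (anyNA(out)) stop("no preset rank for some sequence", call. = FALSE)
  out
}

registerS3method("predict_rank", "fixed_rank_predictor",
                 predict_rank.fixed_rank_predictor,
                 envir = asNamespace("epiself"))

# build a fixed-rank predictor that gives allele `al` a bound fraction
# `frac[al]` over the given epitopes (first fraction*n epitopes bind)
fraction_predictor <- function(fracs, epitopes) {
  n <- length(epitopes)
  ranks <- lapply(fracs, function(f) {
    nb <- round(f * n)
    setNames(c(rep(5, nb), rep(50, n - nb)), epitopes)
  })
  fixed_rank_predictor(ranks)
}
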