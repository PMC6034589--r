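# Pluggable MHC class II binding-predictor interface.
#
# The pipeline only ever asks a predictor for the rank percentile of a
# (peptide, allele) combination: lower means stronger predicted binding, and
# rank <= 10 defines a binder by default. Production runs would plug in an
# external tool such as NetMHCIIpan behind this generic; the package ships a
# deterministic mock predictor whose binder rates can be planted per allele
# and per epitope group, so every downstream stage is testable offline.

#' Predict the binding rank percentile of peptides for an allele
#'
#' @param predictor a predictor object (see [mock_predictor()]).
#' @param sequence character vector of peptide sequences (length >= 9 each).
#' @param allele a single allele designation or DQ pair name known to the
#'   predictor.
#' @param ... passed to methods.
#' @return numeric vector of rank percentiles in `[0, 100]`, one per
#'   sequence; deterministic for fixed inputs and predictor state.
#' @export
predict_rank <- function(predictor, sequence, allele, ...) {
  UseMethod("predict_rank")
}

#' Deterministic mock binding predictor
#'
#' Maps each (sequence, allele) combination to a reproducible rank percentile
#' via a keyed hash, warped so that the probability of `rank <= 10` equals a
#' planted binder rate. Rates are looked up per (allele, tag), where the tag
#' of a sequence (e.g. its species or disease) is supplied as a named vector;
#' combinations without a planted rate fall back to `default_rate`.
#'
#' @param alleles character vector of allele designations / DQ pair names the
#'   predictor knows.
#' @param seed integer key folded into the hash.
#' @param default_rate baseline probability that a peptide is a binder
#'   (`rank <= 10`).
#' @param rate_table optional `data.frame` with columns `allele`, `tag`,
#'   `rate` planting binder rates per allele and sequence tag.
#' @param seq_tags optional named character vector mapping sequences to tags.
#' @return an object of class `mock_predictor`.
#' @examples
#' p <- mock_predictor("DRB1*01:01", seed = 7)
#' predict_rank(p, "ACDEFGHIKLMNPQR", "DRB1*01:01")
#' @export
mock_predictor <- function(alleles, seed = 1L, default_rate = 0.15,
                           rate_table = NULL, seq_tags = NULL) {
  stopifnot(length(alleles) >= 1, default_rate > 0, default_rate < 1)
  if (!is.null(rate_table)) {
    stopifnot(all(c("allele", "tag", "rate") %in% names(rate_table)))
    if (any(rate_table$rate <= 0 | rate_table$rate >= 1)) {
      stop("planted binder rates must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  structure(list(alleles = as.character(alleles),
                 seed = as.integer(seed),
                 default_rate = default_rate,
                 rate_table = rate_table,
                 seq_tags = seq_tags),
            class = "mock_predictor")
}

#' @export
predict_rank.mock_predictor <- function(predictor, sequence, allele, ...) {
  stopifnot(length(allele) == 1L)
  if (!allele %in% predictor$alleles) {
    stop("unknown allele: ", allele, call. = FALSE)
  }
  if (any(nchar(sequence) < 9L)) {
    stop("predictor requires sequences of length >= 9", call. = FALSE)
  }
  rate <- rep.int(predictor$default_rate, length(sequence))
  if (!is.null(predictor$rate_table)) {
    tags <- if (is.null(predictor$seq_tags)) rep(NA_character_, length(sequence))
            else unname(predictor$seq_tags[sequence])
    key <- paste(allele, tags, sep = "\r")
    idx <- match(key, paste(predictor$rate_table$allele,
                            predictor$rate_table$tag, sep = "\r"))
    hit <- !is.na(idx)
    rate[hit] <- predictor$rate_table$rate[idx[hit]]
  }
  u <- hash_unit(paste(predictor$seed, allele, sequence, sep = "|"))
  ifelse(u < rate,
         10 * u / rate,
         10 + 90 * (u - rate) / (1 - rate))
}

#' @export
print.mock_predictor <- function(x, ...) {
  cat("mock MHC-II binding predictor\n",
      "  alleles: ", length(x$alleles), "\n",
      "  seed: ", x$seed, "; default binder rate: ", x$default_rate, "\n",
      "  planted rates: ",
      if (is.null(x$rate_table)) 0 else nrow(x$rate_table), "\n", sep = "")
  invisible(x)
}

#' Serialise / load a mock predictor specification
#'
#' The specification is written as JSON so that a synthetic bundle on disk
#' fully determines the predictions of later pipeline runs.
#'
#' @param predictor a `mock_predictor`.
#' @param path file path.
#' @return `write_predictor()` returns `path` invisibly; `read_predictor()`
#'   returns the reconstructed `mock_predictor`.
#' @export
write_predictor <- function(predictor, path) {
  stopifnot(inherits(predictor, "mock_predictor"))
  spec <- list(type = "mock",
               seed = predictor$seed,
               default_rate = predictor$default_rate,
               alleles = predictor$alleles,
               rate_table = predictor$rate_table,
               seq_tags = as.list(predictor$seq_tags))
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(spec$type, "mock")) {
    stop("unsupported predictor spec type: ", spec$type, call. = FALSE)
  }
  tags <- NULL
  if (length(spec$seq_tags)) {
    tags <- unlist(spec$seq_tags)
  }
  rate_table <- spec$rate_table
  if (!is.null(rate_table) && !nrow(rate_table)) rate_table <- NULL
  mock_predictor(alleles = spec$alleles, seed = spec$seed,
                 default_rate = spec$default_rate,
                 rate_table = rate_table, seq_tags = tags)
}

#' Fraction of peptides predicted to bind an allele
#'
#' @param sequences character vector of peptides.
#' @param allele allele designation or DQ pair name.
#' @param predictor predictor object.
#' @param rank_cutoff binder cutoff on the rank percentile (default 10,
#'   inclusive).
#' @return fraction of `sequences` with `rank <= rank_cutoff`.
#' @export
binding_fraction <- function(sequences, allele, predictor, rank_cutoff = 10) {
  stopifnot(length(sequences) >= 1)
  mean(predict_rank(predictor, sequences, allele) <= rank_cutoff)
}
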