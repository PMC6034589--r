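# Pipeline configuration.
#
# One flat configuration object houses every tunable constant of the
# analysis; defaults are the values used throughout the pipeline (binder
# rank cutoff 10%, redundancy threshold 0.5, rare cutoffs 0/2/5, common
# cutoff 30, ten thousand permutations, corrected significance 0.1,
# association significance 1e-5).

#' Pipeline configuration
#'
#' @param rank_cutoff binder cutoff on the predictor rank percentile
#'   (inclusive).
#' @param redundancy_threshold k-tuple distance threshold of the redundancy
#'   filter, in `(0, 1)`.
#' @param ktuple_k word length of the k-tuple distance.
#' @param kmer_k word length of the proteome-similarity k-mers.
#' @param rare_cutoffs occurrence cutoffs defining rare k-mers.
#' @param common_cutoff occurrence cutoff defining common k-mers.
#' @param n_permutations label-permutation iterations.
#' @param min_species_epitopes minimum species-specific epitopes for a
#'   species to enter the analysis.
#' @param p_corr_threshold BH-corrected significance threshold.
#' @param association_p_threshold significance threshold for disease
#'   associations.
#' @param seed root seed; stages derive their own seeds from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(rank_cutoff = 10,
                       redundancy_threshold = 0.5,
                       ktuple_k = 2L,
                       kmer_k = 5L,
                       rare_cutoffs = c(0L, 2L, 5L),
                       common_cutoff = 30L,
                       n_permutations = 10000L,
                       min_species_epitopes = 25L,
                       p_corr_threshold = 0.1,
                       association_p_threshold = 1e-5,
                       seed = 1L) {
  stopifnot(rank_cutoff >= 0, rank_cutoff <= 100,
            redundancy_threshold > 0, redundancy_threshold < 1,
            ktuple_k >= 1, kmer_k >= 1,
            all(rare_cutoffs >= 0), common_cutoff >= 0,
            n_permutations >= 1,
            p_corr_threshold > 0, p_corr_threshold <= 1,
            association_p_threshold > 0, association_p_threshold <= 1)
  structure(list(rank_cutoff = rank_cutoff,
                 redundancy_threshold = redundancy_threshold,
                 ktuple_k = as.integer(ktuple_k),
                 kmer_k = as.integer(kmer_k),
                 rare_cutoffs = as.integer(rare_cutoffs),
                 common_cutoff = as.integer(common_cutoff),
                 n_permutations = as.integer(n_permutations),
                 min_species_epitopes = as.integer(min_species_epitopes),
                 p_corr_threshold = p_corr_threshold,
                 association_p_threshold = association_p_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("epiself run configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = ",")))
  }
  invisible(x)
}

#' Write / read a configuration as a flat key-value file
#'
#' @param config a [run_config()].
#' @param path file path (tab-delimited `key<TAB>value`, vectors
#'   comma-separated).
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(nm) {
    paste0(nm, "\t", paste(format(config[[nm]], scientific = FALSE,
                                  trim = TRUE), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vals <- lapply(parts, function(p) as.numeric(strsplit(p[2], ",")[[1]]))
  names(vals) <- vapply(parts, `[[`, "", 1L)
  do.call(run_config, vals)
}
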