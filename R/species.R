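# Species specificity of DQ and DR presentation.
#
# Two complementary views are computed per pathogen species: (i) a
# prediction-based recognition matrix (fraction of the species' epitopes
# bound by each DRB1 allele and DQ allele pair) that is scaled, centered and
# Ward-clustered to reveal DQ/DR grouping; and (ii) an in-vitro-style
# confirmation using position-specific scoring matrices trained on DQ- and
# DR-associated epitopes, compared by Wilcoxon rank-sum tests with
# Benjamini-Hochberg correction across species.

.collapse_proteome <- function(proteome) {
  if (is.data.frame(proteome)) proteome <- proteome$sequence
  # '-' never occurs in the amino-acid alphabet, so matches cannot span
  # two proteins
  paste(proteome, collapse = "-")
}

#' Keep species-specific epitopes
#'
#' An epitope is species specific when its sequence occurs as a substring in
#' exactly one of the supplied proteomes. Species left with fewer than
#' `min_epitopes` specific epitopes are dropped from the analysis.
#'
#' @param epitopes_by_species named list: species -> character vector of
#'   epitope sequences.
#' @param proteomes_by_species named list: species -> protein sequences (or
#'   [read_fasta()] output). Every analysed species must have a proteome.
#' @param min_epitopes minimum surviving epitopes per species (default 25).
#' @return named list of the surviving species' specific epitopes.
#' @export
species_specific_filter <- function(epitopes_by_species, proteomes_by_species,
                                    min_epitopes = 25L) {
  missing <- setdiff(names(epitopes_by_species), names(proteomes_by_species))
  if (length(missing)) {
    stop("no proteome supplied for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  blobs <- vapply(proteomes_by_species, .collapse_proteome, "")
  out <- lapply(epitopes_by_species, function(eps) {
    if (!length(eps)) return(character(0))
    hits <- vapply(eps, function(e) {
      sum(vapply(blobs, function(b) grepl(e, b, fixed = TRUE), logical(1)))
    }, 0L)
    eps[hits == 1L]
  })
  out[lengths(out) >= min_epitopes]
}

#' Allele-by-species recognition matrix
#'
#' Entry `(allele, species)` is the fraction of the species' epitopes
#' predicted to bind the allele (rank percentile `<= rank_cutoff`).
#'
#' @param epitopes_by_species named list: species -> epitope sequences.
#' @param dr_alleles character vector of DRB1 designations.
#' @param dq_pairs DQ pair names, or a `data.frame` from
#'   [generate_dq_pairs()].
#' @param predictor binding predictor (see [predict_rank()]).
#' @param rank_cutoff binder cutoff (default 10).
#' @return numeric matrix (rows: DR alleles then DQ pairs; columns: species)
#'   with a `"group"` attribute giving `"DR"`/`"DQ"` per row.
#' @export
recognition_matrix <- function(epitopes_by_species, dr_alleles, dq_pairs,
                               predictor, rank_cutoff = 10) {
  if (is.data.frame(dq_pairs)) dq_pairs <- dq_pairs$pair
  rows <- c(dr_alleles, dq_pairs)
  group <- c(rep("DR", length(dr_alleles)), rep("DQ", length(dq_pairs)))
  mat <- matrix(NA_real_, length(rows), length(epitopes_by_species),
                dimnames = list(rows, names(epitopes_by_species)))
  for (sp in names(epitopes_by_species)) {
    eps <- epitopes_by_species[[sp]]
    for (al in rows) {
      mat[al, sp] <- binding_fraction(eps, al, predictor,
                                      rank_cutoff = rank_cutoff)
    }
  }
  attr(mat, "group") <- setNames(group, rows)
  mat
}

#' Scale, center and Ward-cluster a recognition matrix
#'
#' Each species column is centered to mean 0 and scaled to unit variance;
#' rows (alleles) are then clustered on Euclidean distance with Ward's
#' criterion in the squared-distance (`"ward.D2"`) formulation.
#'
#' @param matrix a [recognition_matrix()] (or any numeric matrix with at
#'   least 2 rows and 2 columns).
#' @param k_clusters number of clusters cut from the tree (default 2,
#'   the DQ/DR split).
#' @return a list of class `recognition_clustering`: `linkage` (an
#'   `hclust`), `order` (row order), `clusters` (cluster labels at the cut)
#'   and `scaled` (the scaled matrix).
#' @export
scale_and_cluster <- function(matrix, k_clusters = 2L) {
  stopifnot(nrow(matrix) >= 2, ncol(matrix) >= 2)
  grp <- attr(matrix, "group")
  sds <- apply(matrix, 2, sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (any(zero_var)) {
    warning("zero-variance column(s) left centered but unscaled: ",
            paste(colnames(matrix)[zero_var], collapse = ", "), call. = FALSE)
  }
  scl <- ifelse(zero_var, FALSE, TRUE)
  sc <- scale(matrix, center = TRUE, scale = sds * as.numeric(scl) + as.numeric(zero_var))
  attributes(sc)$`scaled:center` <- NULL
  attributes(sc)$`scaled:scale` <- NULL
  h <- hclust(dist(sc), method = "ward.D2")
  structure(list(linkage = h,
                 order = h$order,
                 clusters = cutree(h, k = k_clusters),
                 group = grp,
                 scaled = sc),
            class = "recognition_clustering")
}

#' Export a clustering linkage as a Newick tree
#'
#' @param clustering a `recognition_clustering` or an `hclust`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_linkage_newick <- function(clustering, path) {
  h <- if (inherits(clustering, "recognition_clustering")) clustering$linkage
       else clustering
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Per-species DQ/DR mean recognition ratio
#'
#' @param matrix a [recognition_matrix()] (must carry the `"group"` row
#'   attribute, or supply `groups`).
#' @param groups optional `"DQ"`/`"DR"` vector per row.
#' @return named numeric vector: per species, mean over DQ rows divided by
#'   mean over DR rows (`Inf`, with a warning, when the DR mean is 0).
#' @export
dq_dr_ratio <- function(matrix, groups = attr(matrix, "group")) {
  if (is.null(groups)) stop("no row group information", call. = FALSE)
  stopifnot(any(groups == "DQ"), any(groups == "DR"))
  dq <- colMeans(matrix[groups == "DQ", , drop = FALSE])
  dr <- colMeans(matrix[groups == "DR", , drop = FALSE])
  if (any(dr == 0)) {
    warning("DR mean recognition is 0 for: ",
            paste(colnames(matrix)[dr == 0], collapse = ", "),
            "; ratio reported as Inf", call. = FALSE)
  }
  dq / dr
}

#' Position-specific scoring matrix from 15-mer epitopes
#'
#' Entry `[position, residue]` is the relative frequency of the residue at
#' that position in the training set, so each position row sums to 1 and
#' scores are comparable across training sets of different sizes. Epitopes
#' of the examined species can be excluded for leave-one-species-out use.
#'
#' @param training_epitopes `data.frame` with columns `sequence` (15-mers)
#'   and optionally `species`, or a character vector of 15-mers.
#' @param exclude_species species label(s) to leave out.
#' @return a 15 x 20 numeric matrix of class `scoring_matrix` (rows
#'   positions, columns [AA_ALPHABET]) with an `n_epitopes` attribute.
#' @export
build_scoring_matrix <- function(training_epitopes, exclude_species = NULL) {
  if (is.character(training_epitopes)) {
    training_epitopes <- data.frame(sequence = training_epitopes,
                                    stringsAsFactors = FALSE)
  }
  df <- training_epitopes
  if (!is.null(exclude_species) && !is.null(df$species)) {
    df <- df[!df$species %in% exclude_species, , drop = FALSE]
  }
  seqs <- df$sequence[!grepl("X", df$sequence, fixed = TRUE)]
  if (!length(seqs)) {
    stop("empty training set after species exclusion", call. = FALSE)
  }
  if (any(nchar(seqs) != 15L)) {
    stop("training epitopes must be exactly 15 amino acids long",
         call. = FALSE)
  }
  n <- length(seqs)
  mat <- matrix(0, 15L, length(AA_ALPHABET),
                dimnames = list(paste0("p", 1:15), AA_ALPHABET))
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = 15L)
  for (pos in 1:15) {
    tab <- table(factor(chars[pos, ], levels = AA_ALPHABET))
    mat[pos, ] <- as.numeric(tab) / n
  }
  structure(mat, class = c("scoring_matrix", "matrix"), n_epitopes = n)
}

#' Score a 15-mer under a scoring matrix
#'
#' The score is the sum over the 15 positions of the matrix entry for the
#' peptide's residue at that position; it lies in `[0, 15]`. Longer
#' sequences must be decomposed first with [decompose_15mers()].
#'
#' @param matrix a [build_scoring_matrix()] result.
#' @param peptide a peptide of length exactly 15.
#' @return the binding-probability score.
#' @export
score_peptide <- function(matrix, peptide) {
  if (nchar(peptide) != 15L) {
    stop("score_peptide() expects a 15-mer; decompose longer sequences first",
         call. = FALSE)
  }
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  col <- match(res, colnames(matrix))
  # unknown residues (X) contribute nothing
  sum(matrix[cbind(which(!is.na(col)), col[!is.na(col)])])
}

#' Overlapping 15-mer windows of a sequence
#'
#' @param sequence amino-acid sequence of length >= 15.
#' @return character vector of all overlapping 15-mers, in order.
#' @export
decompose_15mers <- function(sequence) {
  if (nchar(sequence) < 15L) {
    stop("sequence shorter than 15 amino acids", call. = FALSE)
  }
  .tuples(sequence, 15L)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotonicity enforced,
#' clipped at 1), via [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Score-based species preference of DQ vs DR
#'
#' For each species, scoring matrices are rebuilt from the DQ- and
#' DR-associated training sets with the species' own epitopes excluded
#' (leave-one-species-out); every overlapping 15-mer of the species'
#' epitopes is scored under both matrices and the two score samples are
#' compared with a Wilcoxon rank-sum test. P-values are Benjamini-Hochberg
#' adjusted across species.
#'
#' @param epitopes_by_species named list: species -> epitope sequences
#'   (length >= 15 each).
#' @param dq_training,dr_training training epitopes (`data.frame` with
#'   `sequence` and `species` columns) for the DQ and DR matrices.
#' @param p_corr_threshold corrected significance threshold (default 0.1).
#' @param paired use a paired signed-rank test on the per-15-mer score pairs
#'   instead of the default unpaired rank-sum test.
#' @return `data.frame` (one row per species): `species`,
#'   `n_scored_15mers`, `raw_p`, `p_corr`, `direction` (`"DQ"`/`"DR"`, the
#'   group with the larger median score), `dq_dr_ratio` (ratio of median
#'   scores), `significant`. The per-species score samples are attached as
#'   attribute `"scores"`.
#' @export
species_preference_test <- function(epitopes_by_species, dq_training,
                                    dr_training, p_corr_threshold = 0.1,
                                    paired = FALSE) {
  species <- names(epitopes_by_species)
  rows <- list(); scores <- list()
  for (sp in species) {
    eps <- epitopes_by_species[[sp]]
    eps <- eps[nchar(eps) >= 15L]
    mers <- unlist(lapply(eps, decompose_15mers), use.names = FALSE)
    if (length(mers) < 2L) {
      warning("species ", sp, " skipped: fewer than 2 scored 15-mers",
              call. = FALSE)
      next
    }
    dq_mat <- build_scoring_matrix(dq_training, exclude_species = sp)
    dr_mat <- build_scoring_matrix(dr_training, exclude_species = sp)
    dq_scores <- vapply(mers, score_peptide, 0, matrix = dq_mat)
    dr_scores <- vapply(mers, score_peptide, 0, matrix = dr_mat)
    wt <- suppressWarnings(
      wilcox.test(dq_scores, dr_scores, paired = paired, exact = FALSE))
    med_dq <- median(dq_scores); med_dr <- median(dr_scores)
    rows[[sp]] <- data.frame(
      species = sp,
      n_scored_15mers = length(mers),
      raw_p = wt$p.value,
      direction = if (med_dq >= med_dr) "DQ" else "DR",
      dq_dr_ratio = med_dq / med_dr,
      stringsAsFactors = FALSE)
    scores[[sp]] <- list(dq = unname(dq_scores), dr = unname(dr_scores))
  }
  if (!length(rows)) stop("no species with enough scored 15-mers",
                          call. = FALSE)
  res <- do.call(rbind, rows)
  res$p_corr <- bh_adjust(res$raw_p)
  res$significant <- res$p_corr < p_corr_threshold
  res <- res[c("species", "n_scored_15mers", "raw_p", "p_corr",
               "direction", "dq_dr_ratio", "significant")]
  rownames(res) <- NULL
  attr(res, "scores") <- scores
  res
}
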