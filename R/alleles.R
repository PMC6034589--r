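# HLA allele name handling and DQ alpha/beta pair enumeration.
#
# DQ heterodimers are encoded by a DQA1 and a DQB1 allele; the unit of DQ
# binding throughout the pipeline is therefore the allele *pair*, written
# "DQA1*xx:yy/DQB1*zz:ww". DRB1 alleles stand alone.

#' Locus of an allele designation
#'
#' @param x character vector of allele designations or pair names.
#' @return character vector: `"DQA1"`, `"DQB1"`, `"DRB1"` or `"DQ_pair"` for
#'   alpha/beta pair names containing `/`.
#' @export
allele_locus <- function(x) {
  out <- rep(NA_character_, length(x))
  out[grepl("/", x, fixed = TRUE)] <- "DQ_pair"
  for (loc in c("DQA1", "DQB1", "DRB1")) {
    out[is.na(out) & startsWith(x, loc)] <- loc
  }
  if (anyNA(out)) {
    stop("unrecognised allele designation: ", deparse(x[is.na(out)][1]),
         call. = FALSE)
  }
  out
}

#' DQ vs DR group of an allele or pair
#'
#' @param x character vector of allele designations or DQ pair names.
#' @return character vector with values `"DQ"` or `"DR"`.
#' @export
allele_group <- function(x) {
  ifelse(allele_locus(x) == "DRB1", "DR", "DQ")
}

#' Pair name of a DQA1/DQB1 combination
#' @param alpha DQA1 designation(s).
#' @param beta DQB1 designation(s).
#' @return character vector of pair names `alpha/beta`.
#' @export
pair_name <- function(alpha, beta) paste(alpha, beta, sep = "/")

#' Split pair names back into alpha and beta designations
#' @param pairs character vector of pair names.
#' @return `data.frame` with columns `alpha`, `beta`.
#' @export
split_pair <- function(pairs) {
  parts <- strsplit(pairs, "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("not a DQ pair name: ", deparse(pairs[bad][1]),
                     call. = FALSE)
  data.frame(alpha = vapply(parts, `[[`, "", 1L),
             beta = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Enumerate DQA1-DQB1 allele pairs
#'
#' Generates all alpha/beta combinations of the supplied catalogs and removes
#' forbidden combinations (alpha/beta pairs that do not form a stable
#' heterodimer). Forbidden entries that name alleles absent from the catalogs
#' simply never match (a warning is emitted).
#'
#' @param dqa1_list character vector of DQA1 designations.
#' @param dqb1_list character vector of DQB1 designations.
#' @param forbidden `data.frame` with columns `dqa1`, `dqb1`, or `NULL`.
#' @return `data.frame` with columns `alpha`, `beta`, `pair`, ordered
#'   alpha-major then beta.
#' @examples
#' generate_dq_pairs(c("DQA1*01:01", "DQA1*02:01"),
#'                   c("DQB1*02:01", "DQB1*03:02"),
#'                   data.frame(dqa1 = "DQA1*01:01", dqb1 = "DQB1*03:02"))
#' @export
generate_dq_pairs <- function(dqa1_list, dqb1_list, forbidden = NULL) {
  stopifnot(length(dqa1_list) > 0, length(dqb1_list) > 0)
  if (!all(startsWith(dqa1_list, "DQA1")))
    stop("dqa1_list entries must be DQA1 designations", call. = FALSE)
  if (!all(startsWith(dqb1_list, "DQB1")))
    stop("dqb1_list entries must be DQB1 designations", call. = FALSE)
  grid <- expand.grid(beta = dqb1_list, alpha = dqa1_list,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("alpha", "beta")]
  grid <- grid[order(match(grid$alpha, dqa1_list),
                     match(grid$beta, dqb1_list)), , drop = FALSE]
  if (!is.null(forbidden) && nrow(forbidden)) {
    unknown <- !(forbidden$dqa1 %in% dqa1_list & forbidden$dqb1 %in% dqb1_list)
    if (any(unknown)) {
      warning(sum(unknown), " forbidden pair(s) reference alleles absent from",
              " the catalogs and never match", call. = FALSE)
    }
    key <- paste(grid$alpha, grid$beta)
    fkey <- paste(forbidden$dqa1, forbidden$dqb1)
    grid <- grid[!key %in% fkey, , drop = FALSE]
  }
  grid$pair <- pair_name(grid$alpha, grid$beta)
  rownames(grid) <- NULL
  grid
}

#' Pairs containing a given DQ allele
#' @param pairs `data.frame` from [generate_dq_pairs()].
#' @param allele a DQA1 or DQB1 designation.
#' @return subset of `pairs` whose alpha or beta equals `allele`.
#' @export
pairs_containing <- function(pairs, allele) {
  loc <- allele_locus(allele)
  if (loc == "DQA1") pairs[pairs$alpha == allele, , drop = FALSE]
  else if (loc == "DQB1") pairs[pairs$beta == allele, , drop = FALSE]
  else stop("pairs_containing() expects a DQA1 or DQB1 allele", call. = FALSE)
}
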