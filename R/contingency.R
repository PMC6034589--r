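# Paired DQ/DR assay counting and Fisher's exact test.
#
# The comparison is restricted to epitopes tested in vitro against at least
# one DQ allele (or DQ pair) AND at least one DR allele; positive/negative
# counts are tallied per assay result, not per epitope.

#' Epitopes tested against both DQ and DR
#'
#' @param assays `data.frame` with columns `epitope_id` and `allele` (allele
#'   designations or DQ pair names).
#' @param assay_classes assay classes to include (default MHC binding assays
#'   only; add `"t_cell"` to pool T-cell assays).
#' @return character vector of epitope ids with at least one DQ and one DR
#'   assay.
#' @export
paired_epitope_subset <- function(assays,
                                  assay_classes = "mhc_binding") {
  stopifnot(all(c("epitope_id", "allele") %in% names(assays)))
  if (!is.null(assays$assay_class)) {
    assays <- assays[assays$assay_class %in% assay_classes, , drop = FALSE]
  }
  if (!nrow(assays)) return(character(0))
  grp <- allele_group(assays$allele)
  dq_ids <- unique(assays$epitope_id[grp == "DQ"])
  dr_ids <- unique(assays$epitope_id[grp == "DR"])
  intersect(dq_ids, dr_ids)
}

#' 2x2 allele-group by outcome contingency table
#'
#' @param assays assay `data.frame` (`epitope_id`, `allele`, `outcome`,
#'   optionally `assay_class`).
#' @param epitope_subset epitope ids to count, typically from
#'   [paired_epitope_subset()].
#' @param assay_classes assay classes to include.
#' @param per_epitope if `TRUE`, collapse to one record per
#'   (epitope, group): positive if any assay was positive. Default counts
#'   each assay result.
#' @return 2x2 integer matrix with rows `DQ`, `DR` and columns `positive`,
#'   `negative`.
#' @export
build_contingency <- function(assays, epitope_subset,
                              assay_classes = "mhc_binding",
                              per_epitope = FALSE) {
  if (!length(epitope_subset)) {
    stop("empty epitope subset: nothing was tested on both DQ and DR",
         call. = FALSE)
  }
  if (!is.null(assays$assay_class)) {
    assays <- assays[assays$assay_class %in% assay_classes, , drop = FALSE]
  }
  assays <- assays[assays$epitope_id %in% epitope_subset, , drop = FALSE]
  grp <- factor(allele_group(assays$allele), levels = c("DQ", "DR"))
  out <- factor(assays$outcome, levels = c("positive", "negative"))
  if (per_epitope) {
    key <- paste(assays$epitope_id, grp)
    any_pos <- tapply(out == "positive", key, any)
    grp <- factor(sub("^.* ", "", names(any_pos)), levels = c("DQ", "DR"))
    out <- factor(ifelse(any_pos, "positive", "negative"),
                  levels = c("positive", "negative"))
  }
  tab <- table(grp, out)
  mat <- matrix(as.integer(tab), 2, 2,
                dimnames = list(c("DQ", "DR"), c("positive", "negative")))
  mat
}

#' Odds ratio and Fisher's exact test for a 2x2 table
#'
#' The odds ratio is the cross-product ratio `(a*d)/(b*c)`; when any cell is
#' zero the Haldane-Anscombe +0.5 correction is applied and flagged. The
#' p-value is the standard two-sided Fisher exact probability (sum of all
#' tables with fixed margins whose probability does not exceed that of the
#' observed table).
#'
#' @param table 2x2 matrix of non-negative counts (rows: groups, columns:
#'   outcomes).
#' @return a list of class `fisher_or_result`: `odds_ratio`, `p_value`,
#'   `haldane` (correction applied), `degenerate` (a zero margin; OR
#'   undefined, p = 1) and the `table`.
#' @examples
#' fisher_or(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # OR 9
#' @export
fisher_or <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  degenerate <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  if (degenerate) {
    res <- list(odds_ratio = NA_real_, p_value = 1, haldane = FALSE,
                degenerate = TRUE, table = table)
    return(structure(res, class = "fisher_or_result"))
  }
  haldane <- any(table == 0)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  p <- stats::fisher.test(table)$p.value
  structure(list(odds_ratio = or, p_value = p, haldane = haldane,
                 degenerate = FALSE, table = table),
            class = "fisher_or_result")
}

#' @export
print.fisher_or_result <- function(x, ...) {
  print(x$table)
  if (x$degenerate) {
    cat("degenerate margin: OR undefined, p = 1\n")
  } else {
    cat(sprintf("OR: %.4g%s, Fisher exact P: %.4g\n", x$odds_ratio,
                if (x$haldane) " (Haldane-Anscombe corrected)" else "",
                x$p_value))
  }
  invisible(x)
}
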