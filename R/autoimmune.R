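# Auto-epitope binding and autoimmune-disease risk.
#
# Disease associations arrive as (allele, disease) or (amino acid position,
# disease) records with odds ratios. The catalog reports individual DQA1/DQB1
# alleles, but DQ binding is a property of the alpha/beta heterodimer, so the
# binding level of a disease-associated allele is the median bound fraction
# over all common DQ pairs containing it (DRB1 alleles bypass pairing).
# Binding levels are then related to risk by Spearman correlation, an OLS
# model log(OR) ~ fraction + disease + chain, and protective/neutral/risk
# group comparisons.

#' Classify disease associations
#'
#' @param records association `data.frame` (see [read_association_table()]).
#' @param p_threshold significance threshold on the association p-value
#'   (default 1e-5; significant means `p < p_threshold`).
#' @return `records` with an added `class` column: `"risk"` (significant,
#'   OR > 1), `"protective"` (significant, OR < 1), `"not_significant"`, or
#'   `"ambiguous"` (significant with OR exactly 1; warned about).
#' @export
classify_associations <- function(records, p_threshold = 1e-5) {
  sig <- records$p_value < p_threshold
  cls <- ifelse(!sig, "not_significant",
                ifelse(records$odds_ratio > 1, "risk",
                       ifelse(records$odds_ratio < 1, "protective",
                              "ambiguous")))
  if (any(cls == "ambiguous")) {
    warning(sum(cls == "ambiguous"),
            " significant association(s) with OR exactly 1 labelled ambiguous",
            call. = FALSE)
  }
  records$class <- cls
  records
}

#' Filter disease epitopes by reference support
#'
#' Epitopes whose role in disease development is supported by fewer than two
#' references are discarded.
#'
#' @param epitopes `data.frame` with an `n_references` column.
#' @param min_references minimum supporting references (default 2).
#' @return the kept rows.
#' @export
disease_epitope_filter <- function(epitopes, min_references = 2L) {
  stopifnot(!is.null(epitopes$n_references))
  epitopes[epitopes$n_references >= min_references, , drop = FALSE]
}

.median_pair_fraction <- function(pair_names, epitopes, predictor,
                                  rank_cutoff) {
  fr <- vapply(pair_names, function(p) {
    binding_fraction(epitopes, p, predictor, rank_cutoff = rank_cutoff)
  }, 0)
  list(fraction = median(fr), n = length(fr), per_pair = fr)
}

#' Auto-epitope binding level of a disease-associated allele
#'
#' For DQA1/DQB1 alleles, the binding level is the median over all common DQ
#' pairs containing the allele of the fraction of disease epitopes bound;
#' DRB1 alleles are evaluated directly.
#'
#' @param allele allele designation.
#' @param common_pairs `data.frame` from [generate_dq_pairs()] (ignored for
#'   DRB1 alleles).
#' @param epitopes character vector of disease-associated epitope sequences.
#' @param predictor binding predictor.
#' @param rank_cutoff binder cutoff (default 10).
#' @param disease optional disease label carried through.
#' @return one-row `data.frame`: `target`, `chain`, `disease`,
#'   `fraction_bound`, `n_pairs_used`.
#' @export
allele_level_binding <- function(allele, common_pairs, epitopes, predictor,
                                 rank_cutoff = 10, disease = NA_character_) {
  stopifnot(length(epitopes) >= 1)
  loc <- allele_locus(allele)
  if (loc == "DRB1") {
    fr <- binding_fraction(epitopes, allele, predictor,
                           rank_cutoff = rank_cutoff)
    n <- 1L
  } else if (loc %in% c("DQA1", "DQB1")) {
    pp <- pairs_containing(common_pairs, allele)
    if (!nrow(pp)) {
      stop("no common DQ pair contains allele ", allele, call. = FALSE)
    }
    mf <- .median_pair_fraction(pp$pair, epitopes, predictor, rank_cutoff)
    fr <- mf$fraction; n <- mf$n
  } else {
    stop("allele_level_binding() expects a DQA1, DQB1 or DRB1 allele",
         call. = FALSE)
  }
  data.frame(target = allele, chain = loc, disease = disease,
             fraction_bound = fr, n_pairs_used = n, stringsAsFactors = FALSE)
}

#' Target id of an amino-acid association
#' @param chain,position,residue amino-acid locus coordinates.
#' @return character id, e.g. `"DQB1_pos9_D"`.
#' @export
aminoacid_target <- function(chain, position, residue) {
  sprintf("%s_pos%d_%s", chain, as.integer(position), residue)
}

#' Auto-epitope binding level of a disease-associated amino acid
#'
#' Qualifying pairs are the common DQ pairs whose chain-side allele carries
#' `residue` at `position` (1-based within the supplied allele protein
#' sequence); the binding level is the median bound fraction over them.
#'
#' @param chain `"DQA1"` or `"DQB1"`.
#' @param position 1-based position within the allele protein sequences.
#' @param residue single amino-acid letter.
#' @param allele_sequences named character vector: allele designation ->
#'   protein sequence.
#' @param common_pairs `data.frame` from [generate_dq_pairs()].
#' @param epitopes disease-associated epitope sequences.
#' @param predictor binding predictor.
#' @param rank_cutoff binder cutoff (default 10).
#' @param disease optional disease label carried through.
#' @return one-row `data.frame` as in [allele_level_binding()].
#' @export
aminoacid_level_binding <- function(chain, position, residue,
                                    allele_sequences, common_pairs, epitopes,
                                    predictor, rank_cutoff = 10,
                                    disease = NA_character_) {
  stopifnot(chain %in% c("DQA1", "DQB1"), position >= 1)
  side <- if (chain == "DQA1") common_pairs$alpha else common_pairs$beta
  carriers <- names(allele_sequences)[
    nchar(allele_sequences) >= position &
      substr(allele_sequences, position, position) == residue]
  carriers <- carriers[allele_locus(carriers) == chain]
  if (!length(carriers)) {
    stop(sprintf("no %s allele carries %s at position %d",
                 chain, residue, position), call. = FALSE)
  }
  pp <- common_pairs[side %in% carriers, , drop = FALSE]
  if (!nrow(pp)) {
    stop("no common DQ pair involves a carrier allele", call. = FALSE)
  }
  mf <- .median_pair_fraction(pp$pair, epitopes, predictor, rank_cutoff)
  data.frame(target = aminoacid_target(chain, position, residue),
             chain = chain, disease = disease,
             fraction_bound = mf$fraction, n_pairs_used = mf$n,
             stringsAsFactors = FALSE)
}

#' Binding summaries for every association record
#'
#' Convenience driver: computes [allele_level_binding()] /
#' [aminoacid_level_binding()] for each row of an association table against
#' that row's disease epitope set.
#'
#' @param associations association `data.frame`
#'   ([read_association_table()] schema, optionally classified).
#' @param epitopes_by_disease named list: disease -> epitope sequences
#'   (already reference-filtered).
#' @param common_pairs `data.frame` from [generate_dq_pairs()].
#' @param predictor binding predictor.
#' @param allele_sequences named allele protein sequences (needed for
#'   amino-acid rows).
#' @param rank_cutoff binder cutoff.
#' @return `data.frame` with one row per association: binding summary columns
#'   plus `odds_ratio`, `p_value` and (when present) `class`.
#' @export
binding_summaries <- function(associations, epitopes_by_disease, common_pairs,
                              predictor, allele_sequences = NULL,
                              rank_cutoff = 10) {
  rows <- lapply(seq_len(nrow(associations)), function(i) {
    rec <- associations[i, ]
    eps <- epitopes_by_disease[[rec$disease]]
    if (is.null(eps) || !length(eps)) {
      stop("no epitopes for disease ", rec$disease, call. = FALSE)
    }
    smry <- if (rec$target_kind == "allele") {
      allele_level_binding(rec$allele, common_pairs, eps, predictor,
                           rank_cutoff = rank_cutoff, disease = rec$disease)
    } else {
      if (is.null(allele_sequences)) {
        stop("amino-acid associations require allele_sequences", call. = FALSE)
      }
      aminoacid_level_binding(rec$chain, rec$position, rec$residue,
                              allele_sequences, common_pairs, eps, predictor,
                              rank_cutoff = rank_cutoff,
                              disease = rec$disease)
    }
    smry$odds_ratio <- rec$odds_ratio
    smry$p_value <- rec$p_value
    if (!is.null(rec$class)) smry$class <- rec$class
    smry
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation between binding level and disease risk
#'
#' @param summaries `data.frame` with columns `target`, `disease`,
#'   `fraction_bound` (e.g. from [binding_summaries()]).
#' @param associations association table with `odds_ratio` (joined on target
#'   and disease); pass `NULL` if `summaries` already carries `odds_ratio`.
#' @return list: `rho`, `p_value`, `n`.
#' @export
correlate_risk <- function(summaries, associations = NULL) {
  if (!is.null(associations)) {
    key_a <- ifelse(associations$target_kind == "allele", associations$allele,
                    aminoacid_target(associations$chain, associations$position,
                                     associations$residue))
    idx <- match(paste(summaries$target, summaries$disease),
                 paste(key_a, associations$disease))
    summaries$odds_ratio <- associations$odds_ratio[idx]
  }
  ok <- complete.cases(summaries[c("fraction_bound", "odds_ratio")])
  x <- summaries$fraction_bound[ok]
  y <- summaries$odds_ratio[ok]
  if (length(x) < 3) stop("need at least 3 joined rows", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Multivariate risk model log(OR) ~ fraction + disease + chain
#'
#' Ordinary least squares on the natural-log odds ratio with the binding
#' fraction as the continuous predictor and disease and chain as dummy-coded
#' categorical covariates. Per-term variance explained is computed from
#' sequential (type-I) sums of squares in the order fraction, disease,
#' chain. Covariates with a single observed level are dropped from the
#' formula; genuinely aliased designs raise an error naming the terms.
#'
#' @param input `data.frame` with columns `log_odds_ratio` (or `odds_ratio`,
#'   logged internally), `fraction_bound`, `disease`, `chain`.
#' @return an object of class `risk_model_fit`: `slope` (fraction term),
#'   `slope_p`, `terms` (`data.frame` of term, variance explained,
#'   sequential-F p), `r_squared`, `f_p` (overall F-test), `bp_p`
#'   (Breusch-Pagan heteroscedasticity p), `n`, and the underlying `fit`.
#' @export
fit_risk_model <- function(input) {
  df <- as.data.frame(input)
  if (is.null(df$log_odds_ratio)) {
    stopifnot(!is.null(df$odds_ratio))
    df$log_odds_ratio <- log(df$odds_ratio)
  }
  stopifnot(all(c("fraction_bound", "disease", "chain") %in% names(df)),
            all(is.finite(df$log_odds_ratio)),
            all(is.finite(df$fraction_bound)))
  df$disease <- factor(df$disease)
  df$chain <- factor(df$chain)
  terms <- "fraction_bound"
  if (nlevels(df$disease) > 1) terms <- c(terms, "disease")
  if (nlevels(df$chain) > 1) terms <- c(terms, "chain")
  form <- stats::reformulate(terms, response = "log_odds_ratio")
  if (nrow(df) <= length(terms) + 1) {
    stop("more parameters than observations", call. = FALSE)
  }
  fit <- lm(form, data = df)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  an <- anova(fit)
  ss <- an[["Sum Sq"]]
  total_ss <- sum(ss)
  term_names <- rownames(an)
  keep <- term_names != "Residuals"
  terms_df <- data.frame(term = term_names[keep],
                         variance_explained = ss[keep] / total_ss,
                         p = an[["Pr(>F)"]][keep],
                         stringsAsFactors = FALSE)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  f_p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  bp <- tryCatch(lmtest::bptest(fit)$p.value, error = function(e) NA_real_)
  structure(list(slope = unname(coef(fit)["fraction_bound"]),
                 slope_p = sm$coefficients["fraction_bound", "Pr(>|t|)"],
                 slope_ci = suppressMessages(
                   stats::confint(fit)["fraction_bound", ]),
                 terms = terms_df,
                 r_squared = sm$r.squared,
                 f_p = f_p,
                 bp_p = unname(bp),
                 n = nrow(df),
                 fit = fit),
            class = "risk_model_fit")
}

#' @export
print.risk_model_fit <- function(x, ...) {
  cat("risk model: log(OR) ~ fraction_bound (+ disease + chain)\n")
  cat(sprintf("  slope: %.4g (p = %.3g, 95%% CI %.3g .. %.3g)\n",
              x$slope, x$slope_p, x$slope_ci[1], x$slope_ci[2]))
  print(transform(x$terms, variance_explained = round(variance_explained, 3)))
  cat(sprintf("  R^2 = %.3g (F-test p = %.3g), BP p = %.3g, n = %d\n",
              x$r_squared, x$f_p, x$bp_p, x$n))
  invisible(x)
}

#' Protective / neutral / risk group comparison
#'
#' Kruskal-Wallis test across the three allele groups' binding fractions,
#' followed by the three pairwise Wilcoxon rank-sum tests with
#' Benjamini-Hochberg adjustment. Neutral fractions are expected to be
#' computed against the pooled all-disease epitope set.
#'
#' @param protective_fracs,neutral_fracs,risk_fracs numeric vectors of bound
#'   fractions per group (each non-empty).
#' @return list: `kw_p`, `kw_statistic`, `pairwise` (`data.frame` with
#'   contrast, raw and BH-adjusted p), `medians`.
#' @export
group_comparison <- function(protective_fracs, neutral_fracs, risk_fracs) {
  groups <- list(protective = protective_fracs, neutral = neutral_fracs,
                 risk = risk_fracs)
  if (any(lengths(groups) == 0)) {
    stop("every group must contain at least one value", call. = FALSE)
  }
  kw <- suppressWarnings(kruskal.test(groups))
  combos <- list(c("protective", "neutral"),
                 c("protective", "risk"),
                 c("neutral", "risk"))
  raw <- vapply(combos, function(cc) {
    suppressWarnings(wilcox.test(groups[[cc[1]]], groups[[cc[2]]],
                                 exact = FALSE))$p.value
  }, 0)
  pw <- data.frame(contrast = vapply(combos, paste, "", collapse = " vs "),
                   raw_p = raw,
                   p_adj = bh_adjust(raw),
                   stringsAsFactors = FALSE)
  list(kw_p = kw$p.value,
       kw_statistic = unname(kw$statistic),
       pairwise = pw,
       medians = vapply(groups, median, 0))
}
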