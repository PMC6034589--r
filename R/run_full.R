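# End-to-end driver: chains redundancy filtering, the 5-mer permutation
# test, the paired assay contingency analysis, the species-preference
# analysis and the autoimmune risk analysis over a bundle directory (as
# written by make_full_bundle()), producing per-stage TSV reports plus a
# combined summary. Reruns with the same bundle and configuration are
# byte-identical: no stage mutates its inputs and every random draw flows
# from the configured seed.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline on a synthetic bundle
#'
#' @param bundle_dir directory written by [make_full_bundle()].
#' @param config a [run_config()].
#' @param out_dir report directory (created; existing files overwritten).
#' @return invisibly, a list with the per-stage results (`filter`, `kmer`,
#'   `assay`, `species`, `risk`) and `out_dir`.
#' @export
run_full <- function(bundle_dir, config = run_config(), out_dir) {
  stopifnot(dir.exists(bundle_dir), inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bp <- function(...) file.path(bundle_dir, ...)
  op <- function(...) file.path(out_dir, ...)

  log_lines <- c("epiself run-full",
                 paste0("bundle: ", bundle_dir),
                 "configuration:",
                 vapply(names(config), function(nm) {
                   sprintf("  %s = %s", nm,
                           paste(config[[nm]], collapse = ","))
                 }, ""))

  ## stage 1: redundancy filter -------------------------------------------
  filter_res <- .stage("filter", {
    dq <- read_fasta(bp("dq_epitopes.fasta"))
    dr <- read_fasta(bp("dr_epitopes.fasta"))
    kept_dq <- filter_redundant(setNames(dq$sequence, dq$id),
                                threshold = config$redundancy_threshold,
                                k = config$ktuple_k)
    kept_dr <- filter_redundant(setNames(dr$sequence, dr$id),
                                threshold = config$redundancy_threshold,
                                k = config$ktuple_k)
    write_fasta(kept_dq, op("kept_dq.fasta"))
    write_fasta(kept_dr, op("kept_dr.fasta"))
    rep <- data.frame(set = c("DQ", "DR"),
                      n_input = c(nrow(dq), nrow(dr)),
                      n_kept = c(length(kept_dq), length(kept_dr)))
    .write_tsv(rep, op("filter_report.tsv"))
    list(dq = kept_dq, dr = kept_dr, report = rep)
  })

  ## stage 2: 5-mer similarity --------------------------------------------
  kmer_res <- .stage("kmer-test", {
    proteome <- read_fasta(bp("human_proteome.fasta"))
    index <- kmer_occurrence_index(proteome, k = config$kmer_k,
                                   proteome_id = "human")
    kmers <- unique(unlist(lapply(c(filter_res$dq, filter_res$dr), function(e)
      .drop_x(decompose_kmers(e, config$kmer_k))), use.names = FALSE))
    occ <- count_occurrences(kmers, index)
    stats <- rbind(
      data.frame(mode = "rare", cutoff = config$rare_cutoffs),
      data.frame(mode = "common", cutoff = config$common_cutoff))
    tests <- lapply(seq_len(nrow(stats)), function(i) {
      permutation_test(filter_res$dq, filter_res$dr, occ,
                       cutoff = stats$cutoff[i], mode = stats$mode[i],
                       n_iter = config$n_permutations,
                       seed = config$seed + 100L + i)
    })
    stats$fraction_dq <- vapply(tests, function(t) t$fractions[["dq"]], 0)
    stats$fraction_dr <- vapply(tests, function(t) t$fractions[["dr"]], 0)
    stats$observed_diff <- vapply(tests, `[[`, 0, "observed_diff")
    stats$p_value <- vapply(tests, `[[`, 0, "p_value")
    .write_tsv(stats, op("kmer_test.tsv"))
    prof_dq <- rarity_profile(filter_res$dq, occ)
    prof_dr <- rarity_profile(filter_res$dr, occ)
    occs <- sort(unique(as.integer(c(names(prof_dq$per_occurrence),
                                     names(prof_dr$per_occurrence)))))
    prof <- data.frame(occurrence = occs,
                       fraction_dq = as.numeric(
                         prof_dq$per_occurrence[as.character(occs)]),
                       fraction_dr = as.numeric(
                         prof_dr$per_occurrence[as.character(occs)]))
    prof[is.na(prof)] <- 0
    .write_tsv(prof, op("kmer_profiles.tsv"))
    list(tests = stats, profiles = prof)
  })

  ## stage 3: paired assay contingency ------------------------------------
  assay_res <- .stage("assay-or", {
    tab <- read_epitope_table(bp("assays.tsv"))
    subset <- paired_epitope_subset(tab$assays)
    ct <- build_contingency(tab$assays, subset)
    fr <- fisher_or(ct)
    rep <- data.frame(dq_positive = ct["DQ", "positive"],
                      dq_negative = ct["DQ", "negative"],
                      dr_positive = ct["DR", "positive"],
                      dr_negative = ct["DR", "negative"],
                      n_paired_epitopes = length(subset),
                      odds_ratio = fr$odds_ratio, p_value = fr$p_value)
    .write_tsv(rep, op("assay_or.tsv"))
    list(table = ct, fisher = fr, n_paired = length(subset))
  })

  ## stage 4: species preference ------------------------------------------
  species_res <- .stage("species", {
    sdir <- bp("species")
    meta <- .read_tsv(file.path(sdir, "species_meta.tsv"))
    meta <- meta[!as.logical(meta$obligate_intracellular), , drop = FALSE]
    eps_tab <- read_epitope_table(file.path(sdir, "epitopes.tsv"))$epitopes
    eps_by_sp <- split(eps_tab$sequence, eps_tab$source_organism)
    eps_by_sp <- eps_by_sp[intersect(names(eps_by_sp), meta$species)]
    eps_by_sp <- lapply(eps_by_sp, filter_redundant,
                        threshold = config$redundancy_threshold,
                        k = config$ktuple_k)
    proteomes <- setNames(lapply(meta$proteome_path, function(p)
      read_fasta(file.path(sdir, p))), meta$species)
    eps_by_sp <- species_specific_filter(
      eps_by_sp, proteomes, min_epitopes = config$min_species_epitopes)
    dr_alleles <- read_allele_catalog(file.path(sdir, "alleles_drb1.txt"),
                                      "DRB1")
    pairs <- generate_dq_pairs(
      read_allele_catalog(file.path(sdir, "alleles_dqa1.txt"), "DQA1"),
      read_allele_catalog(file.path(sdir, "alleles_dqb1.txt"), "DQB1"),
      read_forbidden_pairs(file.path(sdir, "forbidden.tsv")))
    predictor <- read_predictor(file.path(sdir, "predictor.json"))
    rec <- recognition_matrix(eps_by_sp, dr_alleles, pairs, predictor,
                              rank_cutoff = config$rank_cutoff)
    clus <- scale_and_cluster(rec)
    export_linkage_newick(clus, op("species_linkage.nwk"))
    ratios <- dq_dr_ratio(rec)
    rec_df <- data.frame(allele = rownames(rec),
                         group = unname(attr(rec, "group")), rec,
                         check.names = FALSE, row.names = NULL)
    .write_tsv(rec_df, op("recognition_matrix.tsv"))
    # score-based confirmation: train on the species classified DQ- vs
    # DR-preferred by the prediction stage (ratio above/below 1)
    pref <- ifelse(ratios > 1, "DQ", "DR")
    training <- function(grp) {
      sel <- names(pref)[pref == grp]
      do.call(rbind, lapply(sel, function(sp)
        data.frame(sequence = eps_by_sp[[sp]], species = sp,
                   stringsAsFactors = FALSE)))
    }
    score_res <- NULL
    if (length(unique(pref)) == 2L) {
      score_res <- species_preference_test(
        eps_by_sp, training("DQ"), training("DR"),
        p_corr_threshold = config$p_corr_threshold)
      out <- score_res
      out$prediction_ratio <- as.numeric(ratios[out$species])
      out$prediction_group <- unname(pref[out$species])
      .write_tsv(out, op("species_results.tsv"))
    } else {
      warning("all species fall on one side of the DQ/DR ratio; ",
              "score-based confirmation skipped", call. = FALSE)
    }
    list(recognition = rec, clustering = clus, ratios = ratios,
         scores = score_res, prediction_group = pref)
  })

  ## stage 5: autoimmune risk ---------------------------------------------
  risk_res <- .stage("risk", {
    rdir <- bp("risk")
    assoc <- read_association_table(file.path(rdir, "associations.tsv"))
    assoc <- classify_associations(
      assoc, p_threshold = config$association_p_threshold)
    eps_tab <- read_epitope_table(file.path(rdir, "epitopes.tsv"))$epitopes
    kept <- disease_epitope_filter(eps_tab)
    eps_by_disease <- split(kept$sequence, kept$source_organism)
    pairs <- generate_dq_pairs(
      read_allele_catalog(file.path(rdir, "alleles_dqa1.txt"), "DQA1"),
      read_allele_catalog(file.path(rdir, "alleles_dqb1.txt"), "DQB1"),
      read_forbidden_pairs(file.path(rdir, "forbidden.tsv")))
    aseq_df <- read_fasta(file.path(rdir, "allele_seqs.fasta"))
    allele_sequences <- setNames(aseq_df$sequence, aseq_df$id)
    predictor <- read_predictor(file.path(rdir, "predictor.json"))

    sig <- assoc[assoc$class %in% c("risk", "protective"), , drop = FALSE]
    smry <- binding_summaries(sig, eps_by_disease, pairs, predictor,
                              allele_sequences = allele_sequences,
                              rank_cutoff = config$rank_cutoff)
    smry$log_odds_ratio <- log(smry$odds_ratio)
    .write_tsv(smry, op("risk_report.tsv"))

    by_kind <- split(seq_len(nrow(sig)), sig$target_kind)
    cors <- lapply(by_kind, function(ix) correlate_risk(smry[ix, ]))
    fits <- lapply(by_kind, function(ix) fit_risk_model(smry[ix, ]))
    model_rows <- do.call(rbind, lapply(names(fits), function(kind) {
      f <- fits[[kind]]
      data.frame(target_kind = kind, n = f$n,
                 spearman_rho = cors[[kind]]$rho,
                 spearman_p = cors[[kind]]$p_value,
                 slope = f$slope, slope_p = f$slope_p,
                 r_squared = f$r_squared, f_p = f$f_p, bp_p = f$bp_p)
    }))
    .write_tsv(model_rows, op("risk_model.tsv"))

    # neutral alleles: common-catalog alleles with no significant
    # association, evaluated against the pooled all-disease epitope set
    catalog <- unique(c(pairs$alpha, pairs$beta))
    sig_alleles <- unique(sig$allele[sig$target_kind == "allele"])
    neutral <- setdiff(catalog, sig_alleles)
    pooled <- unique(unlist(eps_by_disease, use.names = FALSE))
    neutral_fracs <- vapply(neutral, function(al) {
      allele_level_binding(al, pairs, pooled, predictor,
                           rank_cutoff = config$rank_cutoff)$fraction_bound
    }, 0)
    alle <- smry[smry$target %in% sig_alleles, , drop = FALSE]
    gc_res <- group_comparison(
      alle$fraction_bound[alle$class == "protective"],
      unname(neutral_fracs),
      alle$fraction_bound[alle$class == "risk"])
    gc_df <- data.frame(kw_p = gc_res$kw_p,
                        median_protective = gc_res$medians[["protective"]],
                        median_neutral = gc_res$medians[["neutral"]],
                        median_risk = gc_res$medians[["risk"]])
    .write_tsv(cbind(gc_df, setNames(as.data.frame(t(gc_res$pairwise$p_adj)),
                                     paste0("p_adj_",
                                            gsub(" ", "_",
                                                 gc_res$pairwise$contrast)))),
               op("group_comparison.tsv"))
    list(summaries = smry, correlations = cors, fits = fits,
         groups = gc_res, neutral_fracs = neutral_fracs)
  })

  ## summary ---------------------------------------------------------------
  rare0 <- kmer_res$tests[kmer_res$tests$mode == "rare" &
                            kmer_res$tests$cutoff == config$rare_cutoffs[1], ]
  summary_df <- data.frame(
    quantity = c("kept_dq", "kept_dr", "rare0_diff", "rare0_p",
                 "assay_or", "assay_p", "n_species",
                 "allele_spearman_rho", "allele_slope", "allele_r2",
                 "group_kw_p"),
    value = c(length(filter_res$dq), length(filter_res$dr),
              rare0$observed_diff, rare0$p_value,
              assay_res$fisher$odds_ratio, assay_res$fisher$p_value,
              ncol(species_res$recognition),
              risk_res$correlations[["allele"]]$rho,
              risk_res$fits[["allele"]]$slope,
              risk_res$fits[["allele"]]$r_squared,
              risk_res$groups$kw_p))
  .write_tsv(summary_df, op("summary.tsv"))
  writeLines(log_lines, op("log.txt"))
  invisible(list(filter = filter_res, kmer = kmer_res, assay = assay_res,
                 species = species_res, risk = risk_res, out_dir = out_dir))
}
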