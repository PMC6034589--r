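# Seeded synthetic-data generators.
#
# Every upstream data source of the pipeline (epitope/assay exports, reference
# proteomes, allele catalogs, forbidden-pair lists, allele protein sequences,
# disease-association tables and the binding predictor) is emulated by a
# generator with plantable effect sizes, so each analysis stage can be tested
# for recovery of known ground truth without any download. Generators are
# reproducible: the same seed yields byte-identical files. The planted
# parameters are recorded in a manifest that recovery tests read back.
#
# The generators target the statistical structure of the real inputs (set
# sizes, binder rates, effect sizes), not immunological realism: residues are
# i.i.d. draws, not motif-anchored peptides.

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.random_peptides <- function(n, len = 15L, composition = AA_COMPOSITION) {
  if (n == 0L) return(character(0))
  draws <- sample(AA_ALPHABET, n * len, replace = TRUE, prob = composition)
  apply(matrix(draws, nrow = len), 2, paste, collapse = "")
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate a synthetic proteome
#'
#' Protein sequences with i.i.d. residues from a configurable composition and
#' Poisson-dispersed lengths.
#'
#' @param n_proteins number of proteins (>= 1).
#' @param mean_length mean protein length (>= 5, so 5-mer counting is
#'   possible).
#' @param seed integer seed.
#' @param composition length-20 probability vector over [AA_ALPHABET]
#'   (default [AA_COMPOSITION], natural background frequencies).
#' @param path optional FASTA output path.
#' @param id_prefix record id prefix.
#' @return `data.frame` with columns `id`, `sequence`.
#' @export
make_proteome <- function(n_proteins, mean_length = 300, seed = 1L,
                          composition = AA_COMPOSITION, path = NULL,
                          id_prefix = "prot") {
  stopifnot(n_proteins >= 1)
  if (mean_length < 5) stop("mean_length must be at least 5", call. = FALSE)
  prot <- withr::with_seed(seed, {
    lens <- pmax(5L, rpois(n_proteins, mean_length))
    data.frame(id = sprintf("%s%04d", id_prefix, seq_len(n_proteins)),
               sequence = vapply(lens, function(L) {
                 paste(sample(AA_ALPHABET, L, replace = TRUE,
                              prob = composition), collapse = "")
               }, ""),
               stringsAsFactors = FALSE)
  })
  if (!is.null(path)) write_fasta(prot, path)
  prot
}

# a random 15-mer substring of a random (long enough) protein
.proteome_15mer <- function(seqs, len = 15L) {
  ok <- seqs[nchar(seqs) >= len]
  s <- ok[sample.int(length(ok), 1L)]
  start <- sample.int(nchar(s) - len + 1L, 1L)
  substr(s, start, start + len - 1L)
}

#' Generate DQ/DR epitope sets with a planted human-likeness bias
#'
#' DQ epitopes are 15-mer substrings of the proteome with probability
#' `humanlike_bias` and fully random 15-mers otherwise; DR epitopes are all
#' random. With bias 0 the two sets are exchangeable (permutation-test null);
#' with bias 1 every DQ 5-mer occurs in the proteome.
#'
#' @param proteome proteome sequences or [read_fasta()] output.
#' @param n_dq,n_dr set sizes.
#' @param humanlike_bias planted bias in `[0, 1]`.
#' @param seed integer seed.
#' @param length epitope length (default 15).
#' @return list: `dq`, `dr` (character vectors) and `manifest` (planted
#'   parameters).
#' @export
make_epitope_sets <- function(proteome, n_dq = 200L, n_dr = 200L,
                              humanlike_bias = 0.15, seed = 1L,
                              length = 15L) {
  if (is.data.frame(proteome)) proteome <- proteome$sequence
  stopifnot(humanlike_bias >= 0, humanlike_bias <= 1)
  if (!any(nchar(proteome) >= length)) {
    stop("proteome has no protein of length >= ", length, call. = FALSE)
  }
  withr::with_seed(seed, {
    from_self <- runif(n_dq) < humanlike_bias
    dq <- character(n_dq)
    dq[from_self] <- vapply(seq_len(sum(from_self)), function(i) {
      .proteome_15mer(proteome, length)
    }, "")
    dq[!from_self] <- .random_peptides(sum(!from_self), length)
    dr <- .random_peptides(n_dr, length)
    list(dq = dq, dr = dr,
         manifest = list(humanlike_bias = humanlike_bias,
                         n_dq = n_dq, n_dr = n_dr,
                         n_dq_from_proteome = sum(from_self),
                         seed = seed))
  })
}

#' Generate a paired DQ/DR assay table with a planted odds ratio
#'
#' Each synthetic epitope is tested once against a DQ pair and once against a
#' DRB1 allele; positive rates are chosen so that the expected cross-product
#' ratio of the 2x2 group-by-outcome table equals `target_or`.
#'
#' @param target_or planted odds ratio (> 0).
#' @param n_assays total number of assay results (two per epitope).
#' @param seed integer seed.
#' @param p_dr DR positive rate (the DQ rate is derived from `target_or`).
#' @param path optional TSV output path ([read_epitope_table()] schema).
#' @return list: `table` (the assay rows), `manifest` (generating rates).
#' @export
make_assay_table <- function(target_or = 1.8, n_assays = 2000L, seed = 1L,
                             p_dr = 0.3, path = NULL) {
  stopifnot(target_or > 0, p_dr > 0, p_dr < 1)
  odds_dq <- target_or * p_dr / (1 - p_dr)
  p_dq <- odds_dq / (1 + odds_dq)
  if (!is.finite(p_dq) || p_dq <= 1e-12 || p_dq >= 1 - 1e-12) {
    stop("requested odds ratio pushes the DQ rate outside (0,1)",
         call. = FALSE)
  }
  n_epi <- n_assays %/% 2L
  tab <- withr::with_seed(seed, {
    ids <- sprintf("ep%05d", seq_len(n_epi))
    seqs <- .random_peptides(n_epi)
    dq_pos <- rbinom(n_epi, 1L, p_dq) == 1L
    dr_pos <- rbinom(n_epi, 1L, p_dr) == 1L
    data.frame(
      epitope_id = rep(ids, each = 2L),
      sequence = rep(seqs, each = 2L),
      source_organism = "synthetic pathogen",
      n_references = 2L,
      allele = rep(c("DQA1*01:01/DQB1*02:01", "DRB1*01:01"), n_epi),
      outcome = ifelse(as.vector(rbind(dq_pos, dr_pos)),
                       "positive", "negative"),
      assay_class = "mhc_binding",
      stringsAsFactors = FALSE)
  })
  if (!is.null(path)) .write_tsv(tab, path)
  list(table = tab,
       manifest = list(target_or = target_or, p_dq = p_dq, p_dr = p_dr,
                       n_assays = 2L * n_epi, seed = seed))
}

.species_composition <- function(group, motif_effect) {
  base <- rep(1 / 20, 20)
  pref <- if (group == "DQ") c(rep(1 / 10, 10), rep(0, 10))
          else c(rep(0, 10), rep(1 / 10, 10))
  (1 - motif_effect) * base + motif_effect * pref
}

#' Generate a species-preference bundle
#'
#' Half the species are DQ-preferred, half DR-preferred, on two levels:
#' the mock predictor binds a preferred species' epitopes at
#' `base_rate + preference_effect` (vs `base_rate` otherwise), and each
#' group's species draw their residues from a group-specific composition
#' (mixing weight `motif_effect`), so both the prediction-based clustering
#' and the scoring-matrix confirmation have recoverable ground truth.
#' Species epitopes are substrings of their own proteome only, so they are
#' species specific by construction.
#'
#' @param n_species number of species (>= 2).
#' @param n_dr_alleles,n_dqa1,n_dqb1 catalog sizes.
#' @param n_epitopes_per_species epitopes per species (>= 25 so none is
#'   dropped by the species filter).
#' @param base_rate baseline binder rate.
#' @param preference_effect additional binder rate for the preferred group
#'   (rates must stay inside `[0, 1]`).
#' @param motif_effect mixing weight of the group-specific residue
#'   composition in `[0, 1)`.
#' @param n_proteins,mean_protein_length per-species proteome size.
#' @param seed integer seed.
#' @param outdir optional directory; when given, all files of the bundle are
#'   written there (proteome FASTAs, epitope table, species metadata, allele
#'   catalogs, forbidden pairs, predictor spec, manifest).
#' @return list with `epitopes_by_species`, `proteomes_by_species`,
#'   `dr_alleles`, `dqa1`, `dqb1`, `forbidden`, `pairs`, `predictor`,
#'   `meta`, `dq_training`, `dr_training` and `manifest` (with the planted
#'   group of every species).
#' @export
make_species_bundle <- function(n_species = 6L, n_dr_alleles = 6L,
                                n_dqa1 = 3L, n_dqb1 = 4L,
                                n_epitopes_per_species = 40L,
                                base_rate = 0.1, preference_effect = 0.4,
                                motif_effect = 0.5,
                                n_proteins = 30L, mean_protein_length = 250,
                                seed = 1L, outdir = NULL) {
  stopifnot(n_species >= 2, n_epitopes_per_species >= 1)
  if (base_rate + preference_effect >= 1 || base_rate <= 0) {
    stop("binder rates must stay inside (0, 1)", call. = FALSE)
  }
  species <- sprintf("species_%02d", seq_len(n_species))
  groups <- setNames(rep(c("DQ", "DR"), length.out = n_species), species)
  dr_alleles <- sprintf("DRB1*%02d:01", seq_len(n_dr_alleles))
  dqa1 <- sprintf("DQA1*%02d:01", seq_len(n_dqa1))
  dqb1 <- sprintf("DQB1*%02d:01", seq_len(n_dqb1))
  forbidden <- data.frame(dqa1 = dqa1[1], dqb1 = dqb1[1],
                          stringsAsFactors = FALSE)
  pairs <- generate_dq_pairs(dqa1, dqb1, forbidden)

  proteomes <- list(); epitopes <- list()
  withr::with_seed(seed, {
    for (i in seq_along(species)) {
      sp <- species[i]
      comp <- .species_composition(groups[[sp]], motif_effect)
      lens <- pmax(20L, rpois(n_proteins, mean_protein_length))
      prots <- vapply(lens, function(L) {
        paste(sample(AA_ALPHABET, L, replace = TRUE, prob = comp),
              collapse = "")
      }, "")
      proteomes[[sp]] <- data.frame(
        id = sprintf("%s_prot%03d", sp, seq_len(n_proteins)),
        sequence = prots, stringsAsFactors = FALSE)
      eps <- character(0)
      tries <- 0L
      while (length(eps) < n_epitopes_per_species && tries < 10000L) {
        eps <- unique(c(eps, .proteome_15mer(prots)))
        tries <- tries + 1L
      }
      if (length(eps) < n_epitopes_per_species) {
        stop("could not draw enough distinct epitopes for ", sp,
             call. = FALSE)
      }
      epitopes[[sp]] <- eps[seq_len(n_epitopes_per_species)]
    }
  })

  all_rows <- c(dr_alleles, pairs$pair)
  row_group <- allele_group(all_rows)
  rate_table <- do.call(rbind, lapply(species, function(sp) {
    data.frame(allele = all_rows,
               tag = sp,
               rate = ifelse(row_group == groups[[sp]],
                             base_rate + preference_effect, base_rate),
               stringsAsFactors = FALSE)
  }))
  seq_tags <- unlist(lapply(species, function(sp) {
    setNames(rep(sp, length(epitopes[[sp]])), epitopes[[sp]])
  }))
  predictor <- mock_predictor(alleles = all_rows, seed = seed + 10000L,
                              default_rate = base_rate,
                              rate_table = rate_table, seq_tags = seq_tags)

  training <- function(grp) {
    do.call(rbind, lapply(species[groups == grp], function(sp) {
      data.frame(sequence = epitopes[[sp]], species = sp,
                 stringsAsFactors = FALSE)
    }))
  }
  meta <- data.frame(species = species,
                     proteome_path = sprintf("proteome_%s.fasta", species),
                     obligate_intracellular = FALSE,
                     stringsAsFactors = FALSE)
  bundle <- list(epitopes_by_species = epitopes,
                 proteomes_by_species = proteomes,
                 dr_alleles = dr_alleles, dqa1 = dqa1, dqb1 = dqb1,
                 forbidden = forbidden, pairs = pairs,
                 predictor = predictor, meta = meta,
                 dq_training = training("DQ"), dr_training = training("DR"),
                 manifest = list(groups = groups, base_rate = base_rate,
                                 preference_effect = preference_effect,
                                 motif_effect = motif_effect, seed = seed))
  if (!is.null(outdir)) .write_species_bundle(bundle, outdir)
  bundle
}

.write_species_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(bundle$proteomes_by_species)) {
    write_fasta(bundle$proteomes_by_species[[sp]],
                file.path(outdir, sprintf("proteome_%s.fasta", sp)))
  }
  eps <- do.call(rbind, lapply(names(bundle$epitopes_by_species), function(sp) {
    seqs <- bundle$epitopes_by_species[[sp]]
    data.frame(epitope_id = sprintf("%s_ep%03d", sp, seq_along(seqs)),
               sequence = seqs, source_organism = sp, n_references = 2L,
               stringsAsFactors = FALSE)
  }))
  .write_tsv(eps, file.path(outdir, "epitopes.tsv"))
  .write_tsv(bundle$meta, file.path(outdir, "species_meta.tsv"))
  writeLines(bundle$dr_alleles, file.path(outdir, "alleles_drb1.txt"))
  writeLines(bundle$dqa1, file.path(outdir, "alleles_dqa1.txt"))
  writeLines(bundle$dqb1, file.path(outdir, "alleles_dqb1.txt"))
  .write_tsv(bundle$forbidden, file.path(outdir, "forbidden.tsv"))
  write_predictor(bundle$predictor, file.path(outdir, "predictor.json"))
  .write_manifest(bundle$manifest, file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}

#' Generate an autoimmune-association bundle with a planted slope
#'
#' Each allele of the DQ catalogs receives a planted binding propensity:
#' associated alleles sit `group_effect` above (protective) or below (risk)
#' the neutral centre 0.5, and every DQ pair's binder rate is the mean of its
#' two propensities. Disease epitopes, allele protein sequences and a mock
#' predictor are generated, the *realised* auto-epitope binding level of each
#' associated target is computed with the package's own pipeline, and the
#' log odds ratio is drawn as
#' `slope * (fraction - 0.5) + disease_offset + N(0, noise_sd)`, so that
#' with `noise_sd = 0` and a single disease the regression recovers `slope`
#' exactly.
#'
#' The default sizes mirror the published study design this module emulates:
#' six autoimmune diseases, 22 allele-level and 61 amino-acid-level
#' associations over common-catalog DQA1/DQB1 alleles, with the remaining
#' catalog alleles forming the neutral group.
#'
#' @param slope planted regression slope of log(OR) on bound fraction.
#' @param n_dqa1,n_dqb1 catalog sizes.
#' @param n_diseases number of diseases.
#' @param n_assoc_alleles number of disease-associated alleles (>= 2; half
#'   protective, half risk).
#' @param n_aa_associations number of amino-acid-level associations.
#' @param n_epitopes_per_disease epitopes generated per disease.
#' @param noise_sd residual standard deviation of log(OR) (>= 0).
#' @param group_effect propensity separation of protective/risk alleles from
#'   the neutral centre.
#' @param seed integer seed.
#' @param outdir optional directory to write the bundle files to.
#' @return list with `associations` (classified table), `epitopes` (table
#'   rows; `source_organism` carries the disease label),
#'   `epitopes_by_disease` (reference-filtered sequences), `dqa1`, `dqb1`,
#'   `forbidden`, `pairs`, `allele_sequences`, `predictor` and `manifest`
#'   (planted slope, propensities, offsets, group of every allele).
#' @export
make_association_bundle <- function(slope = -2, n_dqa1 = 14L, n_dqb1 = 18L,
                                    n_diseases = 6L, n_assoc_alleles = 22L,
                                    n_aa_associations = 61L,
                                    n_epitopes_per_disease = 60L,
                                    noise_sd = 0.15, group_effect = 0.3,
                                    seed = 1L, outdir = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  stopifnot(n_dqa1 + n_dqb1 >= 5, n_assoc_alleles >= 2,
            n_assoc_alleles <= n_dqa1 + n_dqb1)
  dqa1 <- sprintf("DQA1*%02d:01", seq_len(n_dqa1))
  dqb1 <- sprintf("DQB1*%02d:01", seq_len(n_dqb1))
  alleles <- c(dqa1, dqb1)
  forbidden <- data.frame(dqa1 = dqa1[1], dqb1 = dqb1[1],
                          stringsAsFactors = FALSE)
  pairs <- generate_dq_pairs(dqa1, dqb1, forbidden)
  diseases <- sprintf("disease_%s", LETTERS[seq_len(n_diseases)])

  withr::with_seed(seed, {
    # planted propensities: protective high, risk low, neutral centred
    assoc <- sample(alleles, n_assoc_alleles)
    n_prot <- ceiling(n_assoc_alleles / 2)
    group <- setNames(rep("neutral", length(alleles)), alleles)
    group[assoc[seq_len(n_prot)]] <- "protective"
    group[assoc[-seq_len(n_prot)]] <- "risk"
    prop <- setNames(0.5 + runif(length(alleles), -0.05, 0.05), alleles)
    prop[group == "protective"] <- 0.5 + group_effect +
      runif(sum(group == "protective"), -0.1, 0.1)
    prop[group == "risk"] <- 0.5 - group_effect +
      runif(sum(group == "risk"), -0.1, 0.1)
    prop <- .clamp(prop, 0.05, 0.95)

    pair_rate <- .clamp((prop[pairs$alpha] + prop[pairs$beta]) / 2 +
                          rnorm(nrow(pairs), 0, 0.02), 0.02, 0.98)
    rate_table <- do.call(rbind, lapply(diseases, function(d) {
      data.frame(allele = pairs$pair, tag = d, rate = unname(pair_rate),
                 stringsAsFactors = FALSE)
    }))

    allele_sequences <- setNames(.random_peptides(length(alleles), 30L),
                                 alleles)

    ep_rows <- do.call(rbind, lapply(diseases, function(d) {
      seqs <- .random_peptides(n_epitopes_per_disease)
      data.frame(epitope_id = sprintf("%s_ep%03d", d,
                                      seq_len(n_epitopes_per_disease)),
                 sequence = seqs, source_organism = d,
                 n_references = sample(c(1L, 2L, 3L, 4L),
                                       n_epitopes_per_disease,
                                       replace = TRUE,
                                       prob = c(0.15, 0.35, 0.3, 0.2)),
                 stringsAsFactors = FALSE)
    }))
    seq_tags <- setNames(ep_rows$source_organism, ep_rows$sequence)
    predictor <- mock_predictor(alleles = pairs$pair, seed = seed + 20000L,
                                default_rate = 0.15,
                                rate_table = rate_table, seq_tags = seq_tags)
    kept <- disease_epitope_filter(ep_rows)
    epitopes_by_disease <- split(kept$sequence, kept$source_organism)

    # disease baseline shifts are kept modest relative to the planted
    # allele effects so OR-derived class labels track the planted groups
    disease_offset <- setNames(rnorm(n_diseases, 0, 0.1), diseases)
    if (n_diseases == 1L) disease_offset[] <- 0

    assoc_rows <- lapply(assoc, function(al) {
      d <- sample(diseases, 1L)
      smry <- allele_level_binding(al, pairs, epitopes_by_disease[[d]],
                                   predictor, disease = d)
      log_or <- slope * (smry$fraction_bound - 0.5) + disease_offset[[d]] +
        rnorm(1, 0, noise_sd)
      data.frame(target_kind = "allele", allele = al,
                 chain = allele_locus(al), position = NA_integer_,
                 residue = "", disease = d,
                 odds_ratio = exp(log_or), p_value = 1e-8,
                 fraction_bound = smry$fraction_bound,
                 stringsAsFactors = FALSE)
    })
    # weak, non-significant associations for two neutral alleles
    neutral <- names(group)[group == "neutral"]
    weak_rows <- lapply(head(neutral, 2L), function(al) {
      d <- sample(diseases, 1L)
      data.frame(target_kind = "allele", allele = al,
                 chain = allele_locus(al), position = NA_integer_,
                 residue = "", disease = d,
                 odds_ratio = exp(rnorm(1, 0, 0.05)), p_value = 0.5,
                 fraction_bound = NA_real_, stringsAsFactors = FALSE)
    })
    aa_rows <- lapply(seq_len(n_aa_associations), function(i) {
      al <- sample(assoc, 1L)
      chain <- allele_locus(al)
      position <- sample.int(30L, 1L)
      residue <- substr(allele_sequences[[al]], position, position)
      d <- sample(diseases, 1L)
      smry <- aminoacid_level_binding(chain, position, residue,
                                      allele_sequences, pairs,
                                      epitopes_by_disease[[d]], predictor,
                                      disease = d)
      log_or <- slope * (smry$fraction_bound - 0.5) + disease_offset[[d]] +
        rnorm(1, 0, noise_sd)
      data.frame(target_kind = "amino_acid", allele = "",
                 chain = chain, position = position, residue = residue,
                 disease = d, odds_ratio = exp(log_or), p_value = 1e-8,
                 fraction_bound = smry$fraction_bound,
                 stringsAsFactors = FALSE)
    })
    associations <- do.call(rbind, c(assoc_rows, weak_rows, aa_rows))
    fractions <- associations$fraction_bound
    associations$fraction_bound <- NULL
    associations <- classify_associations(associations)

    bundle <- list(associations = associations,
                   epitopes = ep_rows,
                   epitopes_by_disease = epitopes_by_disease,
                   dqa1 = dqa1, dqb1 = dqb1, forbidden = forbidden,
                   pairs = pairs, allele_sequences = allele_sequences,
                   predictor = predictor,
                   manifest = list(slope = slope, noise_sd = noise_sd,
                                   group_effect = group_effect,
                                   groups = group, propensities = prop,
                                   disease_offsets = disease_offset,
                                   realised_fractions = fractions,
                                   seed = seed))
    if (!is.null(outdir)) .write_association_bundle(bundle, outdir)
    bundle
  })
}

.write_association_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  assoc <- bundle$associations
  assoc$class <- NULL
  .write_tsv(assoc, file.path(outdir, "associations.tsv"))
  .write_tsv(bundle$epitopes, file.path(outdir, "epitopes.tsv"))
  write_fasta(data.frame(id = names(bundle$allele_sequences),
                         sequence = unname(bundle$allele_sequences),
                         stringsAsFactors = FALSE),
              file.path(outdir, "allele_seqs.fasta"))
  writeLines(bundle$dqa1, file.path(outdir, "alleles_dqa1.txt"))
  writeLines(bundle$dqb1, file.path(outdir, "alleles_dqb1.txt"))
  .write_tsv(bundle$forbidden, file.path(outdir, "forbidden.tsv"))
  write_predictor(bundle$predictor, file.path(outdir, "predictor.json"))
  .write_manifest(bundle$manifest, file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}

# flat key-value manifest; vectors become one row per element
.write_manifest <- function(manifest, path) {
  flat <- list()
  for (nm in names(manifest)) {
    v <- manifest[[nm]]
    if (length(v) == 1L && is.null(names(v))) {
      flat[[nm]] <- as.character(v)
    } else {
      keys <- if (is.null(names(v))) seq_along(v) else names(v)
      for (i in seq_along(v)) {
        flat[[paste0(nm, ".", keys[i])]] <- as.character(v[[i]])
      }
    }
  }
  df <- data.frame(key = names(flat), value = unlist(flat, use.names = FALSE),
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a flat manifest back as a named character vector
#' @param path manifest TSV path.
#' @return named character vector of planted ground-truth values.
#' @export
read_manifest <- function(path) {
  df <- .read_tsv(path)
  setNames(df$value, df$key)
}

#' Generate a full synthetic bundle on disk
#'
#' Writes every input the end-to-end driver ([run_full()]) needs: a human
#' proteome, DQ/DR epitope sets with a planted human-likeness bias, a paired
#' assay table with a planted odds ratio, a species-preference bundle and an
#' autoimmune-association bundle, plus a top-level manifest.
#'
#' @param outdir bundle directory (created if needed).
#' @param seed integer root seed; sub-generators receive fixed offsets of it.
#' @param humanlike_bias,target_or,species_effect,slope,noise_sd headline
#'   planted effect sizes of the component generators.
#' @param n_kmer_epitopes DQ/DR set size for the 5-mer analysis.
#' @param n_assays assay-table size.
#' @return `outdir`, invisibly.
#' @export
make_full_bundle <- function(outdir, seed = 1L, humanlike_bias = 0.15,
                             target_or = 1.8, species_effect = 0.4,
                             slope = -2, noise_sd = 0.3,
                             n_kmer_epitopes = 200L, n_assays = 2000L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  # ~540k residues: large enough that 5-mer occurrence counts disperse the
  # way real proteome profiles do, small enough for desk-scale runs
  proteome <- make_proteome(1200L, 450, seed = seed + 1L,
                            path = file.path(outdir, "human_proteome.fasta"),
                            id_prefix = "hum")
  sets <- make_epitope_sets(proteome, n_dq = n_kmer_epitopes,
                            n_dr = n_kmer_epitopes,
                            humanlike_bias = humanlike_bias, seed = seed + 2L)
  write_fasta(setNames(sets$dq, sprintf("dq%04d", seq_along(sets$dq))),
              file.path(outdir, "dq_epitopes.fasta"))
  write_fasta(setNames(sets$dr, sprintf("dr%04d", seq_along(sets$dr))),
              file.path(outdir, "dr_epitopes.fasta"))
  make_assay_table(target_or = target_or, n_assays = n_assays,
                   seed = seed + 3L, path = file.path(outdir, "assays.tsv"))
  make_species_bundle(preference_effect = species_effect, seed = seed + 4L,
                      outdir = file.path(outdir, "species"))
  make_association_bundle(slope = slope, noise_sd = noise_sd,
                          seed = seed + 5L,
                          outdir = file.path(outdir, "risk"))
  .write_manifest(list(seed = seed, humanlike_bias = humanlike_bias,
                       target_or = target_or,
                       species_effect = species_effect, slope = slope,
                       noise_sd = noise_sd),
                  file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}
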