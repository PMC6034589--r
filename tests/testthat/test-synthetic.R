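test_that("proteome generation is seeded and respects its contracts", {
  p1 <- make_proteome(10, 100, seed = 91)
  p2 <- make_proteome(10, 100, seed = 91)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 10)
  expect_false(identical(p1, make_proteome(10, 100, seed = 92)))
  expect_error(make_proteome(3, mean_length = 3), "at least 5")
  # degenerate composition: every 5-mer identical
  comp <- c(1, rep(0, 19))
  pd <- make_proteome(3, 50, seed = 93, composition = comp)
  expect_true(all(grepl("^A+$", pd$sequence)))
})

test_that("epitope-set generation plants the human-likeness bias", {
  prot <- make_proteome(10, 200, seed = 94)
  # bias 0: both sets fully random (exchangeable construction)
  s0 <- make_epitope_sets(prot, 30, 30, humanlike_bias = 0, seed = 95)
  expect_equal(s0$manifest$n_dq_from_proteome, 0)
  # bias 1: every DQ 5-mer occurs in the proteome, so rare(0) is 0
  s1 <- make_epitope_sets(prot, 30, 30, humanlike_bias = 1, seed = 96)
  idx <- kmer_occurrence_index(prot)
  prof <- rarity_profile(s1$dq, idx)
  expect_false("0" %in% names(prof$per_occurrence))
  expect_equal(rare_fraction(prof, 0, "rare"), 0)
})

test_that("assay tables store their exact generating rates", {
  at <- make_assay_table(target_or = 1.8, n_assays = 400, seed = 97)
  m <- at$manifest
  expect_equal(m$p_dq / (1 - m$p_dq) / (m$p_dr / (1 - m$p_dr)), 1.8)
  expect_equal(nrow(at$table), 400)
  expect_error(make_assay_table(target_or = 1e9, p_dr = 0.999999),
               "outside")
})

test_that("bundles regenerate byte-identically from a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_full_bundle(d1, seed = 5, n_kmer_epitopes = 40L, n_assays = 200L)
  make_full_bundle(d2, seed = 5, n_kmer_epitopes = 40L, n_assays = 200L)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
})

test_that("generated bundles pass every reader and validator", {
  d <- withr::local_tempdir()
  expect_no_warning(
    make_full_bundle(d, seed = 6, n_kmer_epitopes = 30L, n_assays = 200L))
  expect_no_warning({
    read_fasta(file.path(d, "human_proteome.fasta"))
    read_fasta(file.path(d, "dq_epitopes.fasta"))
    read_epitope_table(file.path(d, "assays.tsv"))
    read_epitope_table(file.path(d, "species", "epitopes.tsv"))
    read_allele_catalog(file.path(d, "species", "alleles_drb1.txt"), "DRB1")
    read_forbidden_pairs(file.path(d, "species", "forbidden.tsv"))
    read_predictor(file.path(d, "species", "predictor.json"))
    read_association_table(file.path(d, "risk", "associations.tsv"))
    read_predictor(file.path(d, "risk", "predictor.json"))
  })
  man <- read_manifest(file.path(d, "manifest.tsv"))
  expect_equal(as.numeric(man[["slope"]]), -2)
  expect_equal(as.numeric(man[["humanlike_bias"]]), 0.15)
})

test_that("the species generator plants recoverable group structure", {
  sb <- make_species_bundle(seed = 7)
  expect_true(all(lengths(sb$epitopes_by_species) >= 25))
  # species-specific by construction: the filter drops nothing
  filt <- species_specific_filter(sb$epitopes_by_species,
                                  sb$proteomes_by_species)
  expect_length(filt, length(sb$epitopes_by_species))
  # planted binder rates are realised in the recognition matrix
  rec <- recognition_matrix(sb$epitopes_by_species, sb$dr_alleles, sb$pairs,
                            sb$predictor)
  grp <- attr(rec, "group")
  for (sp in names(sb$manifest$groups)) {
    pref <- sb$manifest$groups[[sp]]
    pref_mean <- mean(rec[grp == pref, sp])
    other_mean <- mean(rec[grp != pref, sp])
    expect_gt(pref_mean, other_mean + 0.2)
  }
})

test_that("the association generator records realised ground truth", {
  ab <- make_association_bundle(seed = 8, noise_sd = 0)
  sig <- ab$associations[ab$associations$class != "not_significant", ]
  # protective alleles were planted above, risk below, the neutral centre;
  # OR-derived class labels can disagree for borderline alleles whose
  # disease baseline outweighs the allele effect, but must mostly agree
  al <- sig[sig$target_kind == "allele", ]
  grp <- ab$manifest$groups[al$allele]
  expect_gte(mean(al$class == unname(grp)), 0.8)
  # with no noise, log(OR) is an exact affine function of the realised
  # fraction within each disease
  sm <- binding_summaries(al, ab$epitopes_by_disease, ab$pairs, ab$predictor)
  off <- ab$manifest$disease_offsets[al$disease]
  expect_equal(log(al$odds_ratio),
               -2 * (sm$fraction_bound - 0.5) + unname(off),
               tolerance = 1e-12)
})
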