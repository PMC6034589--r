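test_that("species-specific filtering keeps single-proteome epitopes", {
  protA <- c("AAAAACDEFGHIKLMNPQRSTVWYAAAA", "CCCCCCCCCCCCCCCCCCCC")
  protB <- c("YYYYYCDEFGHIKLMNPQRSTVWYYYYY", "DDDDDDDDDDDDDDDDDDDD")
  shared <- "CDEFGHIKLMNPQRS"        # present in both proteomes
  only_a <- "AAAACDEFGHIKLMN"        # spans the A-specific prefix
  eps <- list(spA = c(shared, only_a), spB = character(0))
  out <- species_specific_filter(eps, list(spA = protA, spB = protB),
                                 min_epitopes = 1)
  expect_equal(out$spA, only_a)
  expect_error(species_specific_filter(list(spC = "AAAAA"),
                                       list(spA = protA)), "spC")
})

test_that("species below the epitope minimum are dropped", {
  sb <- make_species_bundle(n_epitopes_per_species = 30, seed = 51)
  filt <- species_specific_filter(sb$epitopes_by_species,
                                  sb$proteomes_by_species, min_epitopes = 25)
  expect_length(filt, length(sb$epitopes_by_species))
  # raising the bar above the per-species count drops every species
  filt2 <- species_specific_filter(sb$epitopes_by_species,
                                   sb$proteomes_by_species, min_epitopes = 31)
  expect_length(filt2, 0)
})

test_that("recognition matrices tally binder fractions per allele and species", {
  eps <- list(sp1 = c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC"),
              sp2 = c("DDDDDDDDDDDDDDD", "EEEEEEEEEEEEEEE"))
  always <- fixed_rank_predictor(list("DRB1*01:01" = 0,
                                      "DQA1*01:01/DQB1*02:01" = 0))
  rec <- recognition_matrix(eps, "DRB1*01:01", "DQA1*01:01/DQB1*02:01",
                            always)
  expect_true(all(rec == 1))
  never <- fixed_rank_predictor(list("DRB1*01:01" = 100,
                                     "DQA1*01:01/DQB1*02:01" = 100))
  expect_true(all(recognition_matrix(eps, "DRB1*01:01",
                                     "DQA1*01:01/DQB1*02:01", never) == 0))
  # hand fixture: DR binds one of two sp1 epitopes, none of sp2
  mixed <- fixed_rank_predictor(list(
    "DRB1*01:01" = setNames(c(5, 50, 50, 50), unlist(eps)),
    "DQA1*01:01/DQB1*02:01" = setNames(c(50, 50, 5, 5), unlist(eps))))
  rec <- recognition_matrix(eps, "DRB1*01:01", "DQA1*01:01/DQB1*02:01", mixed)
  expect_equal(unname(rec["DRB1*01:01", ]), c(0.5, 0))
  expect_equal(unname(rec["DQA1*01:01/DQB1*02:01", ]), c(0, 1))
  expect_warning(ratios <- dq_dr_ratio(rec), "Inf")
  expect_equal(unname(ratios["sp2"]), Inf)
  expect_equal(unname(ratios["sp1"]), 0)
})

test_that("column scaling and Ward clustering behave as specified", {
  set.seed(52)
  m <- matrix(runif(40), 8, 5,
              dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
  cl <- scale_and_cluster(m)
  expect_equal(unname(colMeans(cl$scaled)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(cl$scaled, 2, var)), rep(1, 5), tolerance = 1e-9)
  # duplicate rows merge first, at height 0
  m2 <- rbind(m, r9 = m[1, ])
  cl2 <- scale_and_cluster(m2)
  first <- cl2$linkage$merge[1, ]
  expect_setequal(rownames(m2)[-first], c("r1", "r9"))
  expect_equal(cl2$linkage$height[1], 0)
  # zero-variance columns are centered but not scaled, with a warning
  m3 <- m; m3[, 2] <- 0.7
  expect_warning(cl3 <- scale_and_cluster(m3), "zero-variance")
  expect_equal(unname(cl3$scaled[, 2]), rep(0, 8))
})

test_that("planted two-group recognition structure is recovered exactly", {
  for (s in 1:5) {
    sb <- make_species_bundle(seed = 60 + s)
    rec <- recognition_matrix(sb$epitopes_by_species, sb$dr_alleles,
                              sb$pairs, sb$predictor)
    cl <- scale_and_cluster(rec)
    truth <- as.integer(factor(attr(rec, "group")))
    expect_equal(mclust::adjustedRandIndex(cl$clusters, truth), 1)
  }
})

test_that("scoring matrices are row-normalised prevalence tables", {
  mono <- paste(rep("A", 15), collapse = "")
  m <- build_scoring_matrix(mono)
  expect_true(all(m[, "A"] == 1))
  expect_equal(sum(m), 15)
  expect_equal(score_peptide(m, mono), 15)
  expect_equal(score_peptide(m, paste(rep("C", 15), collapse = "")), 0)

  two <- c(paste0("A", paste(rep("G", 14), collapse = "")),
           paste0("C", paste(rep("G", 14), collapse = "")))
  m2 <- build_scoring_matrix(two)
  expect_equal(unname(m2[1, c("A", "C")]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(m2) - 1) < 1e-9))
  # hand sum: peptide AG...G scores 0.5 at position 1 and 1 elsewhere
  expect_equal(score_peptide(m2, two[1]), 0.5 + 14)
  expect_error(score_peptide(m2, "SHORT"), "15-mer")
  expect_error(build_scoring_matrix("ACDEFGHIKLMNPQ"), "exactly 15")
})

test_that("15-mer decomposition windows are exhaustive and ordered", {
  s15 <- paste(rep("A", 15), collapse = "")
  expect_equal(decompose_15mers(s15), s15)
  s17 <- paste(c(rep("A", 15), "C", "D"), collapse = "")
  expect_length(decompose_15mers(s17), 3)
  expect_error(decompose_15mers(substr(s15, 1, 14)), "shorter")
})

test_that("BH adjustment matches the hand computation and the naive step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.16 / 3, 0.8))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(53)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), naive_bh(p))
  }
})

test_that("species preference testing finds planted motifs and stays null otherwise", {
  sb <- make_species_bundle(seed = 71)
  filt <- sb$epitopes_by_species
  # identical DQ and DR training sets: scores tie, nothing significant
  null_res <- species_preference_test(filt, sb$dq_training, sb$dq_training)
  expect_true(all(null_res$raw_p > 0.9))
  expect_false(any(null_res$significant))
  # planted group motifs: every species detected in its true direction
  res <- species_preference_test(filt, sb$dq_training, sb$dr_training)
  truth <- sb$manifest$groups[res$species]
  expect_equal(res$direction, unname(truth))
  expect_true(all(res$significant))
  expect_true(all(res$p_corr >= res$raw_p))
})
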