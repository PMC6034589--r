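test_that("k-mer decomposition keeps overlaps and multiplicity", {
  expect_length(decompose_kmers(paste(rep("A", 15), collapse = "")), 11)
  expect_equal(decompose_kmers("AAAAAA"), c("AAAAA", "AAAAA"))
  expect_equal(decompose_kmers("ACDEF"), "ACDEF")
  expect_error(decompose_kmers("ACD"), "shorter")
})

test_that("occurrence counting slides windows within proteins only", {
  expect_equal(unname(count_occurrences("AAAAA", "AAAAAA")$counts), 2L)
  expect_equal(unname(count_occurrences("WWWWW", "AAAAAA")$counts), 0L)
  # occurrences never span two proteins
  two <- c("AAAAA", "AAAAA")
  expect_equal(unname(count_occurrences("AAAAA", two)$counts), 2L)
})

test_that("occurrence counting equals a naive substring scan", {
  set.seed(21)
  prots <- vapply(1:20, function(i) {
    paste(sample(AA20[1:4], sample(10:60, 1), replace = TRUE), collapse = "")
  }, "")
  queries <- unique(vapply(1:50, function(i) {
    paste(sample(AA20[1:4], 5, replace = TRUE), collapse = "")
  }, ""))
  occ <- count_occurrences(queries, prots)
  for (q in queries) {
    expect_equal(unname(occ$counts[q]), naive_count(q, prots))
  }
})

test_that("rarity profiles are normalised partitions of epitope 5-mers", {
  ep <- "ACDEFGHIKLMNPQR"
  occ <- count_occurrences(decompose_kmers(ep), "WWWWWWWWWW")
  prof <- rarity_profile(ep, occ)
  expect_equal(unname(prof$per_occurrence["0"]), 1)
  expect_equal(prof$n_kmers, 11)

  set.seed(22)
  prot <- rand_peptides(5, 60)
  eps <- rand_peptides(20)
  kmers <- unique(unlist(lapply(eps, decompose_kmers)))
  occ <- count_occurrences(kmers, prot)
  prof <- rarity_profile(eps, occ)
  expect_equal(sum(prof$per_occurrence), 1, tolerance = 1e-9)
  expect_equal(prof$n_kmers, sum(nchar(eps) - 4))
  # identical 5-mer content gives an identical (scale-free) profile
  prof2 <- rarity_profile(c(eps, eps), occ)
  expect_equal(prof2$per_occurrence, prof$per_occurrence)
  # rare/common fractions partition and are monotone in the cutoff
  expect_equal(rare_fraction(prof, 5, "rare") +
                 rare_fraction(prof, 6, "common"), 1)
  expect_gte(rare_fraction(prof, 2, "rare"), rare_fraction(prof, 0, "rare"))
  # coverage errors name the missing 5-mer
  expect_error(rarity_profile("WWWWWWWWWW", occ), "WWWWW")
})

test_that("permutation test is reproducible and null on identical sets", {
  set.seed(23)
  prot <- rand_peptides(5, 80)
  idx <- kmer_occurrence_index(prot)
  set_a <- rand_peptides(20)
  t1 <- permutation_test(set_a, set_a, idx, 0, "rare", n_iter = 200, seed = 5)
  expect_equal(t1$observed_diff, 0)
  expect_equal(t1$p_value, 1)

  set_b <- rand_peptides(20)
  t2 <- permutation_test(set_a, set_b, idx, 0, "rare", n_iter = 200, seed = 9)
  t3 <- permutation_test(set_a, set_b, idx, 0, "rare", n_iter = 200, seed = 9)
  expect_identical(t2$null_diffs, t3$null_diffs)
  expect_identical(t2$p_value, t3$p_value)
})

test_that("permutation p is invariant to swapping the sets", {
  set.seed(24)
  prot <- rand_peptides(5, 80)
  idx <- kmer_occurrence_index(prot)
  a <- c(rand_peptides(15), substr(prot[1], 1, 15), substr(prot[2], 10, 24))
  b <- rand_peptides(15)
  t_ab <- permutation_test(a, b, idx, 0, "rare", n_iter = 500, seed = 3)
  t_ba <- permutation_test(b, a, idx, 0, "rare", n_iter = 500, seed = 3)
  # swapping the inputs flips the sign convention but not the magnitude test
  expect_equal(t_ab$observed_diff, -t_ba$observed_diff)
  expect_equal(t_ab$p_value, t_ba$p_value, tolerance = 0.05)
})

test_that("a planted human-likeness bias is detected", {
  prot <- make_proteome(20, 200, seed = 31)
  sets <- make_epitope_sets(prot, 150, 150, humanlike_bias = 0.3, seed = 32)
  idx <- kmer_occurrence_index(prot)
  res <- permutation_test(sets$dq, sets$dr, idx, 0, "rare",
                          n_iter = 1000, seed = 33)
  expect_gt(res$observed_diff, 0)  # DQ is the more human-like set
  expect_lt(res$p_value, 0.01)
})
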