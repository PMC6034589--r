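test_that("FASTA reading normalises case and round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "acdef", ">p2", "GHIKL", "MNPQR"), f)
  fa <- read_fasta(f)
  expect_equal(fa$id, c("p1", "p2"))
  expect_equal(fa$sequence, c("ACDEF", "GHIKLMNPQR"))

  g <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fa, g)
  expect_identical(read_fasta(g), fa)
})

test_that("FASTA parse errors are located and empty files are empty tables", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACDEF", ">p1", "GHIKL"), f)
  expect_error(read_fasta(f), "line 1")

  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0)

  writeLines(c(">", "ACDEF"), f)
  expect_error(read_fasta(f), "empty record header")
})

test_that("epitope tables parse, fold outcome case and locate bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "epitope_id\tsequence\tsource_organism\tn_references\tallele\toutcome\tassay_class",
    "e1\tACDEFGHIKLMNPQR\torg1\t2\tDRB1*01:01\tPositive\tmhc_binding",
    "e1\tACDEFGHIKLMNPQR\torg1\t2\tDQA1*01:01/DQB1*02:01\tnegative\tmhc_binding",
    "e2\tYYYYYYYYYYYYYYY\torg2\t1\tDRB1*01:01\tnegative\tt_cell"), f)
  tab <- read_epitope_table(f)
  expect_equal(nrow(tab$assays), 3)
  expect_equal(nrow(tab$epitopes), 2)
  expect_equal(tab$assays$outcome, c("positive", "negative", "negative"))

  writeLines(c("epitope_id\tsequence\tsource_organism",
               "e1\tACDEF1HIK\torg"), f)
  expect_error(read_epitope_table(f), "row 1")

  writeLines(c("epitope_id\tsequence", "e1\tACDEF"), f)
  expect_error(read_epitope_table(f), "missing column")

  writeLines(c("epitope_id\tsequence\tsource_organism\tallele\toutcome",
               "e1\tACDEFGHIK\torg\tDRB1*01:01\tmaybe"), f)
  expect_error(read_epitope_table(f), "outcome")
})

test_that("DQ pair enumeration is the ordered cartesian product minus forbidden", {
  dqa <- c("DQA1*01:01", "DQA1*02:01")
  dqb <- c("DQB1*02:01", "DQB1*03:01", "DQB1*03:02")
  forb <- data.frame(dqa1 = "DQA1*01:01", dqb1 = "DQB1*03:01")
  pairs <- generate_dq_pairs(dqa, dqb, forb)
  expect_equal(nrow(pairs), 5)
  expect_equal(nrow(generate_dq_pairs(dqa, dqb, NULL)), 6)
  all_forb <- expand.grid(dqa1 = dqa, dqb1 = dqb, stringsAsFactors = FALSE)
  expect_equal(nrow(generate_dq_pairs(dqa, dqb, all_forb)), 0)
  # alpha-major deterministic order
  expect_equal(pairs$alpha, c(rep(dqa[1], 2), rep(dqa[2], 3)))
  # unknown forbidden alleles warn and never match
  expect_warning(
    p2 <- generate_dq_pairs(dqa, dqb,
                            data.frame(dqa1 = "DQA1*99:99", dqb1 = dqb[1])),
    "never match")
  expect_equal(nrow(p2), 6)
})

test_that("pair enumeration matches brute force on random catalogs", {
  set.seed(101)
  for (rep in 1:20) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    dqa <- sprintf("DQA1*%02d:01", seq_len(na))
    dqb <- sprintf("DQB1*%02d:01", seq_len(nb))
    nf <- sample(0:(na * nb), 1)
    grid <- expand.grid(dqa1 = dqa, dqb1 = dqb, stringsAsFactors = FALSE)
    forb <- grid[sample(nrow(grid), nf), , drop = FALSE]
    pairs <- generate_dq_pairs(dqa, dqb, forb)
    expect_equal(nrow(pairs), na * nb - nf)
    expect_false(any(paste(pairs$alpha, pairs$beta) %in%
                       paste(forb$dqa1, forb$dqb1)))
  }
})

test_that("mock predictor is deterministic, bounded and rejects unknown alleles", {
  p <- mock_predictor(c("DRB1*01:01", "DQA1*01:01/DQB1*02:01"), seed = 7)
  seqs <- c("ACDEFGHIKLMNPQR", "YYYYYYYYYYWWWWW")
  r1 <- predict_rank(p, seqs, "DRB1*01:01")
  r2 <- predict_rank(p, seqs, "DRB1*01:01")
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0 & r1 <= 100))
  expect_error(predict_rank(p, seqs, "DRB1*99:01"), "unknown allele")
  expect_error(predict_rank(p, "SHORT", "DRB1*01:01"), ">= 9")
  # planted rates are realised as binder frequencies
  rt <- data.frame(allele = "DRB1*01:01", tag = "g", rate = 0.8)
  many <- vapply(1:400, function(i) paste(AA20[(i + 0:14) %% 20 + 1],
                                          collapse = ""), "")
  many <- rand_peptides(400)
  p2 <- mock_predictor("DRB1*01:01", seed = 3, rate_table = rt,
                       seq_tags = setNames(rep("g", 400), many))
  fr <- binding_fraction(many, "DRB1*01:01", p2)
  expect_gt(fr, 0.7); expect_lt(fr, 0.9)
})

test_that("predictor specs survive a disk round trip", {
  rt <- data.frame(allele = "DRB1*01:01", tag = "sp", rate = 0.4,
                   stringsAsFactors = FALSE)
  p <- mock_predictor(c("DRB1*01:01"), seed = 5, default_rate = 0.2,
                      rate_table = rt,
                      seq_tags = c(ACDEFGHIKLMNPQR = "sp"))
  f <- withr::local_tempfile(fileext = ".json")
  write_predictor(p, f)
  q <- read_predictor(f)
  expect_identical(predict_rank(p, "ACDEFGHIKLMNPQR", "DRB1*01:01"),
                   predict_rank(q, "ACDEFGHIKLMNPQR", "DRB1*01:01"))
})

test_that("allele catalogs and association tables are validated", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# catalog", "DQB1*02:01", "", "DQB1*03:02"), f)
  expect_equal(read_allele_catalog(f, "DQB1"), c("DQB1*02:01", "DQB1*03:02"))
  expect_error(read_allele_catalog(f, "DQA1"), "does not begin")

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("target_kind", "allele", "chain", "position", "residue",
                     "disease", "odds_ratio", "p_value", sep = "\t"),
               paste("allele", "DQB1*02:01", "DQB1", "", "", "celiac",
                     "0.5", "1e-9", sep = "\t")), g)
  assoc <- read_association_table(g)
  expect_equal(assoc$odds_ratio, 0.5)
  writeLines(c(paste("target_kind", "allele", "chain", "position", "residue",
                     "disease", "odds_ratio", "p_value", sep = "\t"),
               paste("allele", "DQB1*02:01", "DQB1", "", "", "celiac",
                     "-1", "1e-9", sep = "\t")), g)
  expect_error(read_association_table(g), "positive")
})
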