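test_that("associations are classified against the significance threshold", {
  rec <- data.frame(odds_ratio = c(2, 0.5, 2, 1),
                    p_value = c(1e-6, 1e-6, 1e-4, 1e-7))
  out <- suppressWarnings(classify_associations(rec))
  expect_equal(out$class,
               c("risk", "protective", "not_significant", "ambiguous"))
  expect_warning(classify_associations(rec), "ambiguous")
})

test_that("disease epitopes need at least two supporting references", {
  eps <- data.frame(id = c("a", "b", "c"), n_references = c(1, 2, 5))
  kept <- disease_epitope_filter(eps)
  expect_equal(kept$id, c("b", "c"))
})

test_that("binding fractions follow the inclusive rank cutoff", {
  eps <- c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC", "DDDDDDDDDDDDDDD",
           "EEEEEEEEEEEEEEE")
  p <- fixed_rank_predictor(list(X = setNames(c(5, 9, 11, 50), eps),
                                 Y = setNames(c(50, 60, 70, 80), eps),
                                 Z = setNames(c(1, 2, 3, 10), eps)))
  expect_equal(binding_fraction(eps, "X", p), 0.5)
  expect_equal(binding_fraction(eps, "Y", p), 0)
  expect_equal(binding_fraction(eps, "Z", p), 1)  # 10 is a binder (inclusive)
})

test_that("allele-level binding is the median over containing pairs", {
  dqa <- c("DQA1*01:01", "DQA1*02:01", "DQA1*03:01")
  dqb <- c("DQB1*02:01", "DQB1*03:01")
  pairs <- generate_dq_pairs(dqa, dqb, NULL)
  eps <- rand_peptides(10)
  allele <- "DQB1*02:01"
  mine <- pairs_containing(pairs, allele)$pair
  fr <- setNames(c(0.2, 0.4, 0.6), mine)
  others <- setdiff(pairs$pair, mine)
  p <- fraction_predictor(c(as.list(fr),
                            setNames(as.list(rep(0.9, length(others))),
                                     others)), eps)
  s <- allele_level_binding(allele, pairs, eps, p)
  expect_equal(s$fraction_bound, 0.4)
  expect_equal(s$n_pairs_used, 3)
  # even count: midpoint; order of pairs must not matter
  pairs2 <- pairs[pairs$pair %in% mine[1:2] | !pairs$pair %in% mine, ]
  s2 <- allele_level_binding(allele, pairs2, eps, p)
  s2r <- allele_level_binding(allele, pairs2[rev(seq_len(nrow(pairs2))), ],
                              eps, p)
  expect_equal(s2$fraction_bound, 0.3)
  expect_equal(s2r$fraction_bound, s2$fraction_bound)
  # a DRB1 allele bypasses pairing
  pd <- fraction_predictor(list("DRB1*09:01" = 0.7), eps)
  sd <- allele_level_binding("DRB1*09:01", pairs, eps, pd)
  expect_equal(sd$fraction_bound, 0.7)
  expect_equal(sd$n_pairs_used, 1)
  expect_error(allele_level_binding("DQA1*99:01", pairs, eps, p),
               "DQA1\\*99:01")
})

test_that("amino-acid-level binding selects carrier pairs by residue", {
  dqa <- c("DQA1*01:01", "DQA1*02:01")
  dqb <- c("DQB1*02:01", "DQB1*03:01")
  pairs <- generate_dq_pairs(dqa, dqb, NULL)
  aseq <- c("DQA1*01:01" = "AAAAA", "DQA1*02:01" = "ACAAA",
            "DQB1*02:01" = "DDDDD", "DQB1*03:01" = "DEDDD")
  eps <- rand_peptides(10)
  fr <- setNames(c(0.1, 0.3, 0.5, 0.7), pairs$pair)
  p <- fraction_predictor(as.list(fr), eps)
  # residue carried by every beta allele at position 1: global median
  s_all <- aminoacid_level_binding("DQB1", 1, "D", aseq, pairs, eps, p)
  expect_equal(s_all$fraction_bound, median(c(0.1, 0.3, 0.5, 0.7)))
  # residue unique to DQA1*02:01 at position 2: median over its pairs
  s_one <- aminoacid_level_binding("DQA1", 2, "C", aseq, pairs, eps, p)
  expect_equal(s_one$fraction_bound,
               median(fr[pairs$alpha == "DQA1*02:01"]))
  expect_equal(s_one$target, "DQA1_pos2_C")
  expect_error(aminoacid_level_binding("DQA1", 99, "A", aseq, pairs, eps, p),
               "position 99")
})

test_that("risk correlation recovers perfect monotone relations", {
  s <- data.frame(target = letters[1:5], disease = "d",
                  fraction_bound = (1:5) / 10,
                  odds_ratio = c(5, 4, 3, 2, 1))
  expect_equal(correlate_risk(s)$rho, -1)
  s$odds_ratio <- 1:5
  expect_equal(correlate_risk(s)$rho, 1)
  s$fraction_bound <- 0.5
  expect_error(correlate_risk(s), "constant")
  expect_error(correlate_risk(s[1:2, ]), "at least 3")
})

test_that("the risk model recovers a noise-free planted line exactly", {
  df <- data.frame(fraction_bound = seq(0.1, 0.9, length.out = 8),
                   disease = "d1", chain = "DQB1")
  df$log_odds_ratio <- -2 * df$fraction_bound
  fit <- suppressWarnings(fit_risk_model(df))
  expect_equal(fit$slope, -2)
  expect_equal(fit$r_squared, 1)
  # variance-explained components are a sub-stochastic partition
  expect_true(all(fit$terms$variance_explained >= 0))
  expect_lte(sum(fit$terms$variance_explained), 1 + 1e-9)
})

test_that("the risk model errors on aliased designs", {
  df <- data.frame(fraction_bound = rep(c(0.2, 0.8), 5),
                   disease = rep(c("d1", "d2"), 5),
                   chain = rep(c("DQA1", "DQB1"), 5),
                   log_odds_ratio = rnorm(10))
  # chain is perfectly confounded with disease
  expect_error(fit_risk_model(df), "aliased")
})

test_that("the full covariate model decomposes variance sequentially", {
  set.seed(81)
  n <- 40
  df <- data.frame(fraction_bound = runif(n),
                   disease = sample(c("d1", "d2", "d3"), n, replace = TRUE),
                   chain = sample(c("DQA1", "DQB1"), n, replace = TRUE))
  df$log_odds_ratio <- -2 * df$fraction_bound +
    c(d1 = 0, d2 = 0.5, d3 = -0.5)[df$disease] + rnorm(n, 0, 0.2)
  fit <- fit_risk_model(df)
  expect_equal(fit$terms$term, c("fraction_bound", "disease", "chain"))
  an <- anova(fit$fit)
  expect_equal(fit$terms$variance_explained,
               an[["Sum Sq"]][1:3] / sum(an[["Sum Sq"]]))
  expect_equal(fit$r_squared, sum(fit$terms$variance_explained))
  expect_lt(fit$slope_p, 0.01)
  expect_true(is.finite(fit$bp_p))
})

test_that("group comparison is null on identical groups and orders medians", {
  g <- c(0.2, 0.4, 0.6, 0.3, 0.5)
  res <- group_comparison(g, g, g)
  expect_equal(res$kw_statistic, 0, tolerance = 1e-9)
  expect_gt(res$kw_p, 0.99)
  expect_equal(res$pairwise$p_adj, naive_bh(res$pairwise$raw_p))
  expect_error(group_comparison(g, numeric(0), g), "at least one")
})
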