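test_that("nested ANOVA matches the balanced-design decomposition", {
  for (seed in 1:3) {
    d <- balanced_nested_data(n_identities = 2, reps = 3, seed = seed,
                              effect = 0.5)
    a <- nested_anova(d$y, d$level, d$identity,
                      interactions = "category:identity")
    bf <- bf_nested_ss(d$y, d$category, d$identity, d$level)
    tab <- setNames(a$table$ssq, a$table$factor)
    expect_equal(unname(tab["category"]), bf$category, tolerance = 1e-10)
    expect_equal(unname(tab["identity"]), bf$identity, tolerance = 1e-10)
    expect_equal(unname(tab["category:level"]), bf$level_in_category,
                 tolerance = 1e-10)
    expect_equal(unname(tab["category:identity"]), bf$category_identity,
                 tolerance = 1e-10)
    expect_equal(a$ssq_total, bf$total, tolerance = 1e-10)
    expect_equal(a$ms_error, bf$residual / a$df_error, tolerance = 1e-10)
  }
})

test_that("nested ANOVA detects a pure category effect and demands filled cells", {
  d <- balanced_nested_data(n_identities = 3, reps = 4, seed = 4)
  d$y <- ifelse(d$category == "dog", 2, 0) + rnorm(nrow(d), 0, 1e-3)
  a <- nested_anova(d$y, d$level, d$identity)
  expect_lt(a$table$p[a$table$factor == "category"], 1e-10)
  expect_gt(a$table$p[a$table$factor == "identity"], 0.01)
  # boundary trials are dropped before fitting
  d50 <- rbind(d, data.frame(identity = 1, level = 50, rep = 1,
                             category = "boundary", y = 100))
  a50 <- nested_anova(d50$y, d50$level, d50$identity)
  expect_equal(a50$table$ssq, a$table$ssq, tolerance = 1e-10)
  d1 <- d[!(d$identity == 1 & d$level == 25 & d$rep > 1), ]
  expect_error(nested_anova(d1$y, d1$level, d1$identity), "fewer than 2")
})

test_that("omega-squared follows its defining arithmetic", {
  # two groups [1,1,1] vs [3,3,3]: SSQ_effect 6, df 1, MS_error 0, total 6
  expect_equal(omega_squared(6, 1, 0, 6), 1)
  expect_equal(category_effect_size(c(1, 1, 1, 3, 3, 3),
                                    rep(c("cat", "dog"), each = 3)), 1)
  expect_equal(omega_squared(2.5, 5, 0.5, 10), 0)
  expect_error(omega_squared(1, 1, 0, 0), "positive")
})

test_that("omega-squared is unbiased under the null", {
  set.seed(11)
  w <- replicate(400, category_effect_size(rnorm(40),
                                           rep(c("cat", "dog"), 20)))
  expect_lt(abs(mean(w)), 3 * sd(w) / sqrt(length(w)))
})

test_that("ROC AUC equals the tie-aware pairwise count", {
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_auc(c(5, 6), c(1, 2)), 1)
  # all four pairs with the tie counted one half: (1 + 0.5 + 1 + 1)/4
  expect_equal(roc_auc(c(2, 3), c(1, 2)), 0.875)
  expect_equal(bf_auc(c(2, 3), c(1, 2)), 0.875)
  set.seed(12)
  for (i in 1:20) {
    dog <- sample(0:5, 8, replace = TRUE)
    cat_ <- sample(0:5, 6, replace = TRUE)
    expect_equal(roc_auc(dog, cat_), bf_auc(dog, cat_))
  }
  # complementarity for tie-free data
  dog <- rnorm(7); cat_ <- rnorm(9)
  expect_equal(roc_auc(dog, cat_) + roc_auc(cat_, dog), 1)
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("AUC permutation significance behaves per contract", {
  set.seed(13)
  labels <- rep(c("cat", "dog"), each = 15)
  strong <- c(rnorm(15, 0), rnorm(15, 5))
  rec <- auc_significance(strong, labels, seed = 99)
  expect_true(rec$significant)
  expect_identical(rec$preferred, "dog")
  expect_true(rec$auc > rec$null_mu + 1.96 * rec$null_sigma)
  rec2 <- auc_significance(strong, labels, seed = 99)
  expect_identical(rec, rec2)
  expect_warning(
    flat <- auc_significance(rep(1, 30), labels, seed = 1),
    "degenerate")
  expect_false(flat$significant)
  expect_identical(flat$preferred, "none")
})

test_that("selectivity labels follow the significant-preference pattern", {
  rec <- function(sig, pref) list(significant = sig, preferred = pref)
  expect_identical(classify_selectivity(list(rec(TRUE, "dog"),
                                             rec(TRUE, "dog"),
                                             rec(FALSE, "none"))),
                   "category_selective")
  expect_identical(classify_selectivity(list(rec(TRUE, "dog"),
                                             rec(TRUE, "cat"))),
                   "mixed_selectivity")
  expect_identical(classify_selectivity(list(rec(FALSE, "none"))), "none")
})

test_that("the cat-AUC fold is an involution", {
  expect_equal(cat_auc_transform(0.3), 0.7)
  expect_equal(cat_auc_transform(0.5), 0.5)
  expect_equal(cat_auc_transform(cat_auc_transform(0.81)), 0.81)
})

test_that("choice probability folds and tests correctly", {
  ch <- rep(c("first_interval", "second_interval"), each = 10)
  cp <- choice_probability(c(rnorm(10, 0), rnorm(10, 6)), ch, seed = 3)
  expect_equal(cp$folded_auc, 1)
  expect_true(cp$significant)
  # folding: a second-interval-avoiding neuron scores symmetrically
  rates <- c(5, 4, 3, 2, 1, 1.5)
  ch2 <- c("second_interval", "first_interval", "second_interval",
           "first_interval", "second_interval", "first_interval")
  raw <- roc_auc(rates[ch2 == "second_interval"],
                 rates[ch2 == "first_interval"])
  cp2 <- choice_probability(rates, ch2, seed = 4)
  expect_equal(cp2$folded_auc, max(raw, 1 - raw))
  expect_error(choice_probability(1:4, rep("first_interval", 4)),
               "both choices")
})

test_that("per-neuron session summaries flag the constructed effects", {
  cfg <- generator_config(n_identities = 3, days = 1,
                          n_neurons = c(TE = 4, TEO = 4),
                          category_gain = list(TE = c(6, 0), TEO = c(0, 0)),
                          shared_axis_fraction = 1,
                          repeats_per_image = c(8, 8), seed = 21)
  s <- simulate_session(cfg, 1)
  su <- single_unit_summary(s, include_auc = TRUE, n_perm = 300, seed = 5)
  expect_true(all(su$category_significant[su$region == "TE"]))
  expect_gt(mean(su$omega_category[su$region == "TE"]),
            mean(su$omega_category[su$region == "TEO"]))
  expect_true(all(su$selectivity[su$region == "TE"] ==
                    "category_selective"))
  recs <- attr(su, "auc_records")
  expect_equal(nrow(recs), 8 * 3)
})
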