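# small strong-signal and null sessions for the decoding contracts
strong_session <- function(seed = 31, rho = 1, gain = 4) {
  cfg <- generator_config(n_identities = 4, days = 1,
                          n_neurons = c(TE = 14, TEO = 14),
                          category_gain = list(TE = c(gain, 0),
                                               TEO = c(gain, 0)),
                          shared_axis_fraction = rho,
                          repeats_per_image = c(7, 8), seed = seed)
  simulate_session(cfg, 1)
}

null_session <- function(seed = 32) {
  simulate_session(no_signal_config(n_identities = 4, days = 1,
                                    n_neurons = c(TE = 14, TEO = 14),
                                    repeats_per_image = c(7, 8),
                                    seed = seed), 1)
}

test_that("traditional decoding separates a strong-signal population", {
  dr <- decode_traditional(strong_session(), "TE", n_neurons = 10,
                           n_repeats = 8, seed = 1)
  expect_gt(mean(dr$accuracy), 0.9)
  expect_lt(abs(mean(dr$accuracy_shuffled) - 0.5), 0.1)
})

test_that("traditional decoding is at chance on a no-signal population", {
  dr <- decode_traditional(null_session(), "TE", n_neurons = 10,
                           n_repeats = 12, seed = 2)
  se <- sd(dr$accuracy) / sqrt(length(dr$accuracy))
  expect_lt(abs(mean(dr$accuracy) - 0.5), 3 * se + 0.02)
})

test_that("decoding repeats are deterministic and splits are disjoint", {
  s <- strong_session()
  a <- decode_traditional(s, "TE", n_neurons = 6, n_repeats = 2, seed = 7,
                          diagnostics = TRUE)
  b <- decode_traditional(s, "TE", n_neurons = 6, n_repeats = 2, seed = 7)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$scores, b$scores)
  for (d in a$diagnostics) {
    expect_equal(anyDuplicated(d$trial_row), 0)  # one role per trial
    expect_equal(sum(d$role == "test"), 4 * 10)  # 1 test per image
  }
})

test_that("insufficient trials or neurons are reported", {
  s <- strong_session()
  expect_error(decode_traditional(s, "TE", n_neurons = 6,
                                  trials_per_image = 9),
               "fewer than 9")
  expect_error(decode_traditional(s, "TE", n_neurons = 99, n_repeats = 1),
               "neurons")
})

test_that("generalization folds partition identities and test unseen ones", {
  s <- strong_session()
  dg <- decode_generalization(s, "TE", n_neurons = 8, n_folds = 4,
                              n_repeats = 2, seed = 3, diagnostics = TRUE)
  for (fold_of in dg$diagnostics) {
    expect_setequal(names(fold_of), as.character(1:4))
    expect_equal(sort(as.integer(table(fold_of))), rep(1L, 4))
  }
  # every identity tested once per pass: 10 images x 6 drawn trials each
  expect_equal(nrow(dg$scores), 2 * 4 * 10 * 6)
})

test_that("shared-axis signal generalizes; identity-specific does not", {
  s1 <- strong_session(seed = 41, rho = 1)
  g1 <- decode_generalization(s1, "TE", n_neurons = 10, n_folds = 4,
                              n_repeats = 4, seed = 4)
  expect_gt(mean(g1$accuracy), 0.85)
  s0 <- strong_session(seed = 42, rho = 0)
  g0 <- decode_generalization(s0, "TE", n_neurons = 10, n_folds = 4,
                              n_repeats = 6, seed = 5)
  t0 <- decode_traditional(s0, "TE", n_neurons = 10, n_repeats = 6,
                           seed = 6)
  expect_lt(abs(mean(g0$accuracy) - 0.5), 0.08)
  expect_gt(mean(t0$accuracy), 0.75)
})

test_that("choice decoding runs on boundary trials and is deterministic", {
  cfg <- generator_config(n_identities = 6, days = 1,
                          n_neurons = c(TE = 10, TEO = 10),
                          psychometric = list(slope = 1, bias = 0),
                          repeats_per_image = c(8, 8), seed = 51)
  s <- simulate_session(cfg, 1)
  a <- decode_choice(s, "TE", n_repeats = 4, seed = 8)
  b <- decode_choice(s, "TE", n_repeats = 4, seed = 8)
  expect_identical(a$accuracy, b$accuracy)
  expect_true(all(a$accuracy >= 0 & a$accuracy <= 1))
  # all-boundary-trials-one-choice session is rejected
  s1 <- s
  keep <- s1$trials$morph_level == 50
  s1$trials$choice[keep] <- "first_interval"
  expect_error(decode_choice(s1, "TE", n_repeats = 1), "both choices")
})

test_that("correct-vs-error filtering follows the exclusion rules", {
  # hand-built two-day experiment: 2 identities, training and ambiguous
  # levels, image (1, 0) with too few correct trials on day 2
  build_day <- function(day, n_rep, short_img = FALSE, perf_low = FALSE) {
    stim <- generate_stimulus_set(2, c(0, 35, 65, 100))
    rows <- list()
    for (i in seq_len(nrow(stim))) {
      reps <- if (short_img && stim$morph_identity[i] == 1 &&
                  stim$morph_level[i] == 0) 2 else n_rep
      for (r in seq_len(reps)) {
        dog <- stim$morph_level[i] > 50
        ambig <- stim$morph_level[i] %in% c(35, 65)
        # one error trial per ambiguous image; more errors if perf_low
        err <- (ambig && r == 1) || (perf_low && r <= 3)
        rows[[length(rows) + 1]] <- data.frame(
          day = day, morph_identity = stim$morph_identity[i],
          morph_level = stim$morph_level[i],
          choice = if (xor(dog, err)) "second_interval" else
            "first_interval",
          outcome = if (err) "error" else "correct")
      }
    }
    t <- do.call(rbind, rows)
    t <- cbind(trial_id = seq_len(nrow(t)), t)
    set.seed(100 + day)
    sig <- ifelse(t$morph_level > 50, 3, 0)
    counts <- cbind(matrix(rpois(nrow(t) * 6, lambda = 3 + sig), ncol = 6))
    colnames(counts) <- sprintf("d%d_n%d", day, 1:6)
    neurons <- data.frame(neuron_id = colnames(counts),
                          region = rep(c("TE", "TEO"), each = 3), day = day)
    new_session(day, neurons, t, counts, stim, 0.5)
  }
  s1 <- build_day(1, n_rep = 8)
  s2 <- build_day(2, n_rep = 8, short_img = TRUE)
  s3 <- build_day(3, n_rep = 8, perf_low = TRUE)  # 5/8 correct = 62.5%
  res <- decode_correct_vs_error(list(s1, s2, s3), "TE", n_neurons = 3,
                                 min_correct = 3, n_repeats = 2, seed = 9)
  expect_false(res$days$qualifying[3])
  expect_true("day_below_performance" %in% res$exclusions$reason)
  ex <- res$exclusions
  expect_true(any(ex$reason == "insufficient_correct_trials" &
                    ex$morph_identity == 1 & ex$morph_level == 0))
  expect_true(any(ex$reason == "partner_excluded" &
                    ex$morph_identity == 1 & ex$morph_level == 100))
  expect_setequal(paste(res$training_images$morph_identity,
                        res$training_images$morph_level),
                  c("2 0", "2 100"))
  expect_named(res$per_day, c("1", "2"))
  expect_length(res$per_day[["1"]]$accuracy_correct, 2)
})

test_that("attenuated error signals yield lower error-trial accuracy", {
  cfg <- learning_profile_config(
    "T", days = 4, n_neurons = c(TE = 20, TEO = 4),
    repeats_per_image = c(6, 8),
    category_gain = list(TE = c(3, 0.5), TEO = c(0, 0)),
    psychometric = list(slope = 5, bias = 0),
    shared_axis_fraction = 0.8,
    error_signal_attenuation = 0.2, seed = 61)
  sims <- simulate_learning_experiment(cfg)
  res <- decode_correct_vs_error(sims, "TE", n_neurons = 10,
                                 min_correct = 3, n_repeats = 6, seed = 10)
  ok <- unlist(lapply(res$per_day, `[[`, "accuracy_correct"))
  err <- unlist(lapply(res$per_day, `[[`, "accuracy_error"))
  expect_gt(mean(ok), mean(err) + 0.05)
})
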