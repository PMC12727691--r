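# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no data files.

# hand-built 5-trial, 5-neuron (3 TE + 2 TEO) session with known counts
tiny_session <- function() {
  stim <- generate_stimulus_set(2, c(0, 50, 100))
  trials <- data.frame(
    trial_id = 1:5, day = 1,
    morph_identity = c(1, 1, 2, 2, 1),
    morph_level = c(0, 100, 0, 100, 50),
    choice = c("first_interval", "second_interval", "first_interval",
               "first_interval", "second_interval"),
    outcome = c("correct", "correct", "correct", "error", "neither"),
    stringsAsFactors = FALSE)
  counts <- matrix(
    c(1L, 2L, 3L, 4L, 5L,
      6L, 7L, 8L, 9L, 10L,
      0L, 1L, 0L, 1L, 0L,
      2L, 2L, 2L, 2L, 2L,
      5L, 4L, 3L, 2L, 1L), 5, 5,
    dimnames = list(NULL, c("te1", "te2", "te3", "teo1", "teo2")))
  neurons <- data.frame(neuron_id = c("te1", "te2", "te3", "teo1", "teo2"),
                        region = c("TE", "TE", "TE", "TEO", "TEO"),
                        day = 1, stringsAsFactors = FALSE)
  new_session(1, neurons, trials, counts, stim, 0.5)
}

# generator with no category or level signal: per-neuron category tests
# are null-calibrated under it
no_signal_config <- function(...) {
  args <- list(category_gain = list(TE = c(0, 0), TEO = c(0, 0)),
               level_gain = 0, identity_tuning_sd = 1,
               psychometric = list(slope = 0, bias = 0))
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

# the two-region learning fixture at the suite's problem size
paper_fixture_config <- function(seed) {
  learning_profile_config("T", n_neurons = c(TE = 40, TEO = 40),
                          repeats_per_image = c(6, 8), seed = seed)
}

# brute-force AUC: all pairs, ties counted one half
bf_auc <- function(dog, cat) {
  s <- 0
  for (d in dog) for (c in cat) s <- s + (d > c) + 0.5 * (d == c)
  s / (length(dog) * length(cat))
}

# brute-force BH step-up adjustment
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# classical balanced decomposition of the nested design (category,
# identity, level within category, category x identity), computed from
# cell means; the sequential aov SS must match it on balanced data
bf_nested_ss <- function(y, category, identity, level) {
  grand <- mean(y)
  ss <- function(groups) {
    m <- tapply(y, groups, mean)
    n <- tapply(y, groups, length)
    sum(n * (m - grand)^2)
  }
  ss_cat <- ss(category)
  ss_id <- ss(identity)
  # level within category: deviations of level means from their category mean
  m_cl <- tapply(y, list(category, level), mean)
  n_cl <- tapply(y, list(category, level), length)
  m_c <- tapply(y, category, mean)
  ss_lev <- 0
  for (cc in rownames(m_cl)) for (ll in colnames(m_cl)) {
    if (!is.na(m_cl[cc, ll])) {
      ss_lev <- ss_lev + n_cl[cc, ll] * (m_cl[cc, ll] - m_c[cc])^2
    }
  }
  m_ci <- tapply(y, list(category, identity), mean)
  n_ci <- tapply(y, list(category, identity), length)
  m_i <- tapply(y, identity, mean)
  ss_ci <- 0
  for (cc in rownames(m_ci)) for (ii in colnames(m_ci)) {
    if (!is.na(m_ci[cc, ii])) {
      ss_ci <- ss_ci + n_ci[cc, ii] *
        (m_ci[cc, ii] - m_c[cc] - m_i[ii] + grand)^2
    }
  }
  ss_total <- sum((y - grand)^2)
  lapply(list(category = ss_cat, identity = ss_id,
              level_in_category = ss_lev, category_identity = ss_ci,
              total = ss_total,
              residual = ss_total - ss_cat - ss_id - ss_lev - ss_ci),
         as.numeric)
}

# Toy two-region score simulations for the d' combination taxonomy. Each
# repeat trains the package decoder on a small Gaussian population and
# returns test-trial sigmoid scores; the TEO construction sets the
# information relation between the regions.
sim_ensemble_dprimes <- function(scenario = c("redundant", "complementary",
                                              "noise"),
                                 n_rep = 30, n_channels = 8, mu = 0.25,
                                 n_train = 40, n_val = 10, n_test = 40) {
  scenario <- match.arg(scenario)
  spec <- decoder_spec(max_epochs = 2000)
  one <- function(x_tr, y_tr, x_va, y_va, x_te, y_te) {
    fit <- train_decoder(x_tr, y_tr, x_va, y_va, spec)
    sc <- predict(fit, x_te)
    dprime(sc[y_te == 0], sc[y_te == 1])
  }
  out <- matrix(0, n_rep, 3, dimnames = list(NULL, c("TE", "TEO",
                                                     "combined")))
  n_all <- n_train + n_val + n_test
  for (r in seq_len(n_rep)) {
    y <- rep(0:1, length.out = n_all)
    sig <- matrix(rnorm(n_all * n_channels, (2 * y - 1) * mu), n_all)
    te <- sig
    teo <- switch(scenario,
      redundant = te + matrix(rnorm(n_all * n_channels, 0, 0.3), n_all),
      complementary = matrix(rnorm(n_all * n_channels, (2 * y - 1) * mu),
                             n_all),
      noise = matrix(rnorm(n_all * n_channels, 0, 3), n_all))
    tr <- seq_len(n_train); va <- n_train + seq_len(n_val)
    te_ix <- n_train + n_val + seq_len(n_test)
    for (ens in c("TE", "TEO", "combined")) {
      x <- switch(ens, TE = te, TEO = teo, combined = cbind(te, teo))
      out[r, ens] <- tryCatch(
        one(x[tr, ], y[tr], x[va, ], y[va], x[te_ix, ], y[te_ix]),
        error = function(e) 0)
    }
  }
  out
}

# balanced nested-design data: I identities x 2 levels per category x reps
balanced_nested_data <- function(n_identities = 2, reps = 3, seed = 1,
                                 effect = 0) {
  set.seed(seed)
  levels <- c(25, 40, 60, 75)
  d <- expand.grid(identity = seq_len(n_identities), level = levels,
                   rep = seq_len(reps))
  d$category <- assign_category(d$level)
  d$y <- rnorm(nrow(d)) + effect * (d$category == "dog")
  d
}
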