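# Generative model for a two-region category-learning experiment.
#
# Each neuron's mean rate is
#   baseline + identity tuning + level ramp + category term,
# where the category term magnitude follows a linear per-day schedule
# (initial gain + slope * (day - 1), per region) and its variance is split
# rho:(1 - rho) between a population axis shared across all morph
# identities (weight sqrt(rho)) and an identity-specific axis (weight
# sqrt(1 - rho)), so changing rho reallocates signal without changing its
# total power. rho governs whether category information generalizes across
# morph identities: with rho = 1 a decoder trained on some identities
# transfers to held-out ones; with rho = 0 it cannot.

#' Configuration for the synthetic learning-experiment generator
#'
#' @param n_identities Number of morph identities.
#' @param levels Morph levels; default the standard 11-level sequence.
#' @param days Number of learning days.
#' @param n_neurons Named vector `c(TE = , TEO = )`: neurons recorded per
#'   region on each day (fresh roster every day).
#' @param window_s Response window in seconds.
#' @param baseline_rate Baseline firing rate (Hz).
#' @param category_gain List with elements `TE` and `TEO`, each
#'   `c(initial, slope)` in Hz: category-term magnitude on day d is
#'   `initial + slope * (d - 1)`. A slope of 0 is the null (no-learning)
#'   model.
#' @param shared_axis_fraction rho in \[0, 1\]: fraction of the
#'   category-signal variance carried on the shared (identity-general)
#'   axis, the rest sitting on identity-specific axes. A scalar, one value
#'   per day, or a list with elements `TE` and `TEO` (each scalar or
#'   per-day) for region-specific schedules.
#' @param level_gain Hz per unit of the signed morph-level ramp
#'   `(level - 50)/50`; each neuron's ramp sign is random.
#' @param identity_tuning_sd SD (Hz) of per-neuron, per-identity tuning
#'   offsets.
#' @param dog_preference_prob Probability that a neuron's shared-axis
#'   category sign prefers dog; values > 0.5 emulate dog-dominant
#'   plasticity.
#' @param noise `"poisson"` (counts ~ Poisson(rate * window)) or
#'   `list(type = "gaussian", sd = )` (counts rounded and clipped at 0).
#' @param repeats_per_image `c(min, max)` presentations of each image per
#'   day.
#' @param psychometric List with `slope` and `bias`, each scalar or one
#'   value per day: P(second-interval release) =
#'   `plogis(slope * (level - 50)/50 + bias)`.
#' @param error_signal_attenuation Factor in \[0, 1\] scaling the category
#'   term on error trials (1 = none), emulating weaker category evidence
#'   when the subject errs.
#' @param animal_label Label stored in generated data.
#' @param seed Base seed; day d uses `seed + d`.
#' @return An object of class `generator_config`.
#' @seealso [learning_profile_config()], [null_profile_config()]
#' @export
generator_config <- function(n_identities = 10, levels = morph_levels(),
                             days = 5,
                             n_neurons = c(TE = 15, TEO = 15),
                             window_s = 0.55,
                             baseline_rate = 10,
                             category_gain = list(TE = c(1, 0.5),
                                                  TEO = c(1, 0)),
                             shared_axis_fraction = 0.5,
                             level_gain = 1,
                             identity_tuning_sd = 1,
                             dog_preference_prob = 0.5,
                             noise = "poisson",
                             repeats_per_image = c(6, 14),
                             psychometric = list(slope = 3, bias = 0),
                             error_signal_attenuation = 1,
                             animal_label = "sim",
                             seed = 1L) {
  stopifnot(n_identities >= 1, days >= 1,
            all(c("TE", "TEO") %in% names(n_neurons)),
            length(repeats_per_image) == 2,
            repeats_per_image[1] <= repeats_per_image[2])
  rec <- function(x, what) {
    if (length(x) == 1) rep(x, days)
    else if (length(x) == days) x
    else stop(what, " must have length 1 or days")
  }
  if (!is.list(shared_axis_fraction)) {
    shared_axis_fraction <- list(TE = shared_axis_fraction,
                                 TEO = shared_axis_fraction)
  }
  shared_axis_fraction <- lapply(shared_axis_fraction, rec,
                                 what = "shared_axis_fraction")
  stopifnot(all(unlist(shared_axis_fraction) >= 0),
            all(unlist(shared_axis_fraction) <= 1))
  cfg <- list(
    n_identities = as.integer(n_identities), levels = as.integer(levels),
    days = as.integer(days), n_neurons = n_neurons, window_s = window_s,
    baseline_rate = baseline_rate, category_gain = category_gain,
    shared_axis_fraction = shared_axis_fraction,
    level_gain = level_gain, identity_tuning_sd = identity_tuning_sd,
    dog_preference_prob = dog_preference_prob, noise = noise,
    repeats_per_image = as.integer(repeats_per_image),
    psychometric = list(slope = rec(psychometric$slope, "psychometric$slope"),
                        bias = rec(psychometric$bias, "psychometric$bias")),
    error_signal_attenuation = error_signal_attenuation,
    animal_label = animal_label, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Learning-profile generator preset
#'
#' The two-region learning profile used throughout the package's recovery
#' tests: the TE category gain grows across days while TEO's does not, the
#' shared-axis fraction rho grows with day (so generalization improves),
#' and the psychometric slope steepens so behavior improves in step. Region
#' TEO starts with the larger gain, reproducing the early TEO advantage and
#' the later crossover.
#'
#' @param animal `"T"` (10 identities, 9 days, 550 ms window, 6--14 repeats
#'   per image) or `"X"` (20 identities, 5 days, 530 ms window, 9--10
#'   repeats).
#' @param ... Overrides passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
learning_profile_config <- function(animal = c("T", "X"), ...) {
  animal <- match.arg(animal)
  base <- if (animal == "T") {
    list(n_identities = 10, days = 9, window_s = 0.55,
         repeats_per_image = c(6, 14), n_neurons = c(TE = 15, TEO = 18))
  } else {
    list(n_identities = 20, days = 5, window_s = 0.53,
         repeats_per_image = c(9, 10), n_neurons = c(TE = 87, TEO = 62))
  }
  over <- list(...)
  days <- if (!is.null(over$days)) over$days else base$days
  base$days <- days
  args <- list(
    baseline_rate = 10,
    category_gain = list(TE = c(0.3, 0.45), TEO = c(2, 0)),
    shared_axis_fraction = list(TE = seq(0.35, 0.85, length.out = days),
                                TEO = 0.5),
    level_gain = 1, identity_tuning_sd = 1.5,
    psychometric = list(slope = seq(1, 5, length.out = days), bias = 0),
    animal_label = paste0("sim_", animal))
  args <- c(base, args)
  args[names(over)] <- over
  do.call(generator_config, args)
}

#' Null (no-learning) generator preset
#'
#' Both regions' category-gain slopes are 0 and all day schedules are flat,
#' so every downstream "learning" statistic is null-calibrated.
#'
#' @param ... Overrides passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
null_profile_config <- function(...) {
  args <- list(category_gain = list(TE = c(1, 0), TEO = c(1, 0)),
               shared_axis_fraction = 0.5,
               psychometric = list(slope = 2, bias = 0))
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

#' Draw one day's per-neuron tuning parameters
#'
#' Neurons are independent samples each day (rosters are never tracked
#' across days). Each neuron gets a shared-axis category sign (dog-preferring
#' with probability `dog_preference_prob`), per-identity category signs,
#' per-identity tuning offsets, and a signed level-ramp coefficient.
#'
#' @param config A `generator_config`.
#' @param region `"TE"` or `"TEO"`.
#' @param n Number of neurons.
#' @return List of parameter matrices/vectors used by [mean_rate()].
#' @export
draw_neuron_params <- function(config, region, n) {
  id_n <- config$n_identities
  list(
    region = region,
    shared_sign = sample(c(-1, 1), n, replace = TRUE,
                         prob = c(1 - config$dog_preference_prob,
                                  config$dog_preference_prob)),
    identity_sign = matrix(sample(c(-1, 1), n * id_n, replace = TRUE),
                           n, id_n),
    identity_offset = matrix(rnorm(n * id_n, 0, config$identity_tuning_sd),
                             n, id_n),
    level_slope = config$level_gain * sample(c(-1, 1), n, replace = TRUE)
  )
}

#' Mean firing rate of simulated neurons for one image and day
#'
#' Evaluates the generative model: baseline + identity tuning + signed
#' level ramp + category term, with the category-term magnitude following
#' the per-region day schedule and its variance split rho:(1 - rho)
#' between the shared and identity-specific axes (weights sqrt(rho) and
#' sqrt(1 - rho)), rectified at 0 before noise sampling. Boundary (50%)
#' images receive no category term.
#'
#' @param params Output of [draw_neuron_params()].
#' @param morph_identity,morph_level The image.
#' @param day Day index (1-based).
#' @param config A `generator_config`.
#' @param category_scale Extra factor on the category term (used for
#'   error-trial attenuation).
#' @return Numeric vector of mean rates (Hz), one per neuron, all >= 0.
#' @export
mean_rate <- function(params, morph_identity, morph_level, day, config,
                      category_scale = 1) {
  stopifnot(day >= 1, day <= config$days)
  gain <- config$category_gain[[params$region]]
  g <- category_scale * (gain[1] + gain[2] * (day - 1))
  rho <- config$shared_axis_fraction[[params$region]][day]
  cat_dir <- (morph_level > 50) - (morph_level < 50)  # +1 dog, -1 cat, 0
  axis <- sqrt(rho) * params$shared_sign +
    sqrt(1 - rho) * params$identity_sign[, morph_identity]
  r <- config$baseline_rate +
    params$identity_offset[, morph_identity] +
    params$level_slope * (morph_level - 50) / 50 +
    cat_dir * g * axis
  pmax(r, 0)
}

.sample_counts <- function(rate, window_s, noise) {
  lambda <- rate * window_s
  if (identical(noise, "poisson")) {
    rpois(length(lambda), lambda)
  } else if (is.list(noise) && identical(noise$type, "gaussian")) {
    pmax(0L, as.integer(round(lambda + rnorm(length(lambda), 0, noise$sd))))
  } else stop("unknown noise model")
}

#' Simulate one day's session
#'
#' Presents each image of the morph matrix a random number of times (within
#' `repeats_per_image`), samples spike counts from the noise model around
#' `mean_rate * window`, draws choices from the day's psychometric model
#' P(second-interval release) = logistic(slope * (level - 50)/50 + bias),
#' and scores outcomes (second interval is the dog choice; boundary images
#' are scored "neither"). Fully reproducible from the seed.
#'
#' @param config A `generator_config`.
#' @param day Day index in `1:config$days`.
#' @param seed Seed for this day; defaults to `config$seed + day`.
#' @return A `neural_session`.
#' @export
simulate_session <- function(config, day, seed = config$seed + day) {
  stopifnot(inherits(config, "generator_config"),
            day >= 1, day <= config$days)
  if (sum(config$n_neurons) < 1) stop("empty neuron roster")
  set.seed(seed)
  stim <- generate_stimulus_set(config$n_identities, config$levels)
  params <- list(TE = draw_neuron_params(config, "TE", config$n_neurons[["TE"]]),
                 TEO = draw_neuron_params(config, "TEO",
                                          config$n_neurons[["TEO"]]))
  rep_pool <- config$repeats_per_image[1]:config$repeats_per_image[2]
  n_rep <- rep_pool[sample.int(length(rep_pool), nrow(stim),
                               replace = TRUE)]
  img_idx <- sample(rep(seq_len(nrow(stim)), n_rep))
  n_trials <- length(img_idx)
  lev <- stim$morph_level[img_idx]
  idd <- stim$morph_identity[img_idx]

  sl <- config$psychometric$slope[day]
  bi <- config$psychometric$bias[day]
  p_second <- plogis(sl * (lev - 50) / 50 + bi)
  second <- runif(n_trials) < p_second
  choice <- ifelse(second, "second_interval", "first_interval")
  cat_lab <- assign_category(lev)
  outcome <- ifelse(cat_lab == "boundary", "neither",
                    ifelse((cat_lab == "dog") == second, "correct", "error"))
  is_err <- outcome == "error" & config$error_signal_attenuation < 1

  counts <- matrix(0L, n_trials, sum(config$n_neurons))
  ids <- character(0)
  col0 <- 0
  for (region in c("TE", "TEO")) {
    nn <- config$n_neurons[[region]]
    ids <- c(ids, sprintf("d%02d_%s_%03d", day, region, seq_len(nn)))
    # mean rates per unique image, expanded to trials; error trials use
    # the attenuated category term
    mu <- matrix(vapply(seq_len(nrow(stim)), function(i) {
      mean_rate(params[[region]], stim$morph_identity[i],
                stim$morph_level[i], day, config)
    }, numeric(nn)), nrow = nn)  # nn x images
    mu_err <- if (any(is_err)) {
      matrix(vapply(seq_len(nrow(stim)), function(i) {
        mean_rate(params[[region]], stim$morph_identity[i],
                  stim$morph_level[i], day, config,
                  category_scale = config$error_signal_attenuation)
      }, numeric(nn)), nrow = nn)
    } else mu
    for (j in seq_len(nn)) {
      m <- ifelse(is_err, mu_err[j, img_idx], mu[j, img_idx])
      counts[, col0 + j] <- .sample_counts(m, config$window_s, config$noise)
    }
    col0 <- col0 + nn
  }
  colnames(counts) <- ids
  neurons <- data.frame(
    neuron_id = ids,
    region = rep(c("TE", "TEO"), config$n_neurons[c("TE", "TEO")]),
    day = day, stringsAsFactors = FALSE)
  trials <- data.frame(trial_id = seq_len(n_trials), day = day,
                       morph_identity = idd, morph_level = lev,
                       choice = choice, outcome = outcome,
                       stringsAsFactors = FALSE)
  new_session(day, neurons, trials, counts, stim, config$window_s)
}

#' Simulate a full learning experiment
#'
#' One session per day with an independent neuron roster each day.
#'
#' @param config A `generator_config`.
#' @return List of `neural_session`, one per day.
#' @export
simulate_learning_experiment <- function(config) {
  lapply(seq_len(config$days), function(d) simulate_session(config, d))
}
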