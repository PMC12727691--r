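# End-to-end analysis of a multi-day experiment: per-day single-unit
# statistics, traditional decoding per region, between-category
# dissimilarity, behavioral performance, and the cross-day inference that
# summarizes whether each region learned.

#' Run the full learning analysis on a list of daily sessions
#'
#' For every day and region this computes the fraction of
#' category-significant neurons (nested ANOVA) and their mean one-way
#' effect size, traditional decoding accuracy with its paired shuffled
#' control, the mean cat-vs-dog representational dissimilarity, and the
#' behavioral correct rate; it then fits the cross-day statistics (day
#' slopes per region, region-by-day interactions, and the bootstrap
#' decoding-vs-day and decoding-vs-behavior correlation tests).
#'
#' @param sessions List of `neural_session`, one per day.
#' @param n_neurons Neurons subsampled per decoding repeat.
#' @param trials_per_image Trials drawn per image for decoding.
#' @param n_repeats Decoding repeats per day and region.
#' @param n_boot Bootstrap samples for the correlation tests.
#' @param alpha Significance level for the single-unit category factor.
#' @param seed Optional seed.
#' @param spec A [decoder_spec()].
#' @return List of class `learning_analysis`: `by_day` (per-day, per-region
#'   metric table), `decoding` (repeat-level accuracies), `rsa_pairs`
#'   (pair-level cat-vs-dog dissimilarities), `stats` (the fitted cross-day
#'   inference, per region), `behavior`.
#' @seealso [learning_signature()]
#' @export
run_learning_analysis <- function(sessions, n_neurons = 8,
                                  trials_per_image = 6, n_repeats = 20,
                                  n_boot = 1000, alpha = 0.05,
                                  seed = NULL, spec = decoder_spec()) {
  if (!is.null(seed)) set.seed(seed)
  days <- vapply(sessions, `[[`, 0L, "day")
  regions <- c("TE", "TEO")
  by_day <- list(); dec <- list(); rsa <- list()
  behavior <- vapply(sessions, behavioral_correct_rate, 0)
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    su <- single_unit_summary(s, alpha = alpha)
    for (reg in regions) {
      sr <- su[su$region == reg, ]
      dr <- decode_traditional(s, reg, n_neurons = n_neurons,
                               trials_per_image = trials_per_image,
                               n_repeats = n_repeats, spec = spec)
      ds <- category_dissimilarity_summary(s, reg)
      cd <- ds$pairs[ds$pairs$pair_class == "cat_vs_dog", ]
      by_day[[length(by_day) + 1]] <- data.frame(
        day = days[i], region = reg,
        frac_significant = mean(sr$category_significant),
        mean_omega = mean(sr$omega_category[sr$category_significant]),
        accuracy = mean(dr$accuracy),
        accuracy_shuffled = mean(dr$accuracy_shuffled),
        dissimilarity_catdog = mean(cd$dissimilarity),
        behavior = behavior[i])
      dec[[length(dec) + 1]] <- data.frame(
        day = days[i], region = reg, rep = seq_len(n_repeats),
        accuracy = dr$accuracy, accuracy_shuffled = dr$accuracy_shuffled)
      rsa[[length(rsa) + 1]] <- data.frame(
        day = days[i], region = reg, dissimilarity = cd$dissimilarity)
    }
  }
  by_day <- do.call(rbind, by_day)
  dec <- do.call(rbind, dec)
  rsa <- do.call(rbind, rsa)

  # cross-day fits use one mean per day and region: observations within a
  # day share that day's neuron roster, so repeat- or pair-level fits would
  # overstate the evidence (pseudo-replication)
  stats <- list()
  for (reg in regions) {
    bd <- by_day[by_day$region == reg, ]
    dd <- dec[dec$region == reg, ]
    acc_by_day <- split(dd$accuracy, dd$day)
    shuf_by_day <- split(dd$accuracy_shuffled, dd$day)
    stats[[reg]] <- list(
      frac_fit = fit_day_lm(bd$frac_significant, bd$day),
      acc_fit = fit_day_lm(bd$accuracy, bd$day),
      rsa_fit = fit_day_lm(bd$dissimilarity_catdog, bd$day),
      acc_vs_day = bootstrap_corr_vs_day(acc_by_day, shuf_by_day,
                                         n_boot = n_boot),
      acc_vs_behavior = bootstrap_corr_vs_day(acc_by_day, shuf_by_day,
                                              covariate = behavior,
                                              n_boot = n_boot))
  }
  stats$interaction_acc <- fit_region_day_interaction(
    by_day$accuracy, by_day$region, by_day$day)
  stats$interaction_rsa <- fit_region_day_interaction(
    by_day$dissimilarity_catdog, by_day$region, by_day$day)
  structure(list(by_day = by_day, decoding = dec, rsa_pairs = rsa,
                 stats = stats, behavior = behavior, days = days),
            class = "learning_analysis")
}

#' Qualitative learning signature of an analyzed experiment
#'
#' Checks whether the analysis reproduces the two-region learning pattern:
#' TE-only positive day slopes for the fraction of category-significant
#' neurons, decoding accuracy, and cat-vs-dog dissimilarity; significant
#' region-by-day interactions for accuracy and dissimilarity; and TE-only
#' decoding-behavior correlation. "TE-only" means the TE test is
#' significantly positive while the TEO one is not; the four TEO null
#' tests form one comparison family and their p-values are
#' Benjamini-Hochberg adjusted before the flatness calls.
#'
#' @param analysis A `learning_analysis`.
#' @param alpha Significance level for the component tests.
#' @return Named logical vector with an `all` element.
#' @export
learning_signature <- function(analysis, alpha = 0.05) {
  st <- analysis$stats
  up <- function(fit) fit$slope > 0 && fit$p_slope < alpha
  teo_p <- bh_fdr(c(st$TEO$frac_fit$p_slope, st$TEO$acc_fit$p_slope,
                    st$TEO$rsa_fit$p_slope, st$TEO$acc_vs_behavior$p))
  teo_dir <- c(st$TEO$frac_fit$slope, st$TEO$acc_fit$slope,
               st$TEO$rsa_fit$slope,
               st$TEO$acc_vs_behavior$delta_mean) > 0
  teo_up <- teo_p < alpha & teo_dir
  out <- c(
    te_frac_up = up(st$TE$frac_fit),
    teo_frac_flat = !teo_up[1],
    te_acc_up = up(st$TE$acc_fit),
    teo_acc_flat = !teo_up[2],
    te_rsa_up = up(st$TE$rsa_fit),
    teo_rsa_flat = !teo_up[3],
    interaction_acc = st$interaction_acc$p_interaction < alpha,
    interaction_rsa = st$interaction_rsa$p_interaction < alpha,
    te_behavior = st$TE$acc_vs_behavior$significant &&
      st$TE$acc_vs_behavior$delta_mean > 0,
    teo_behavior_flat = !teo_up[4])
  c(out, all = all(out))
}
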