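# Discriminability of decoder output scores for single and pooled
# ensembles, and the four-way combination taxonomy.

#' Discriminability index d' of two score distributions
#'
#' `d' = |mean_cat - mean_dog| / sqrt(0.5 (var_cat + var_dog))`, computed
#' on decoder output scores of test trials.
#'
#' @param scores_cat,scores_dog Scores of test trials from each category
#'   (at least 2 each).
#' @return Non-negative d'.
#' @export
dprime <- function(scores_cat, scores_dog) {
  if (length(scores_cat) < 2 || length(scores_dog) < 2) {
    stop("need at least 2 scores per class")
  }
  pooled <- 0.5 * (var(scores_cat) + var(scores_dog))
  if (pooled <= 0) stop("zero pooled variance")
  abs(mean(scores_cat) - mean(scores_dog)) / sqrt(pooled)
}

#' Per-repeat d' from a decoding result
#'
#' Applies [dprime()] to every repeat's test-trial scores, cat vs dog. The
#' pre-threshold sigmoid outputs are used by default; the logit scale is
#' available via `scale`.
#'
#' @param result A `decoding_result`.
#' @param scale `"response"` (sigmoid output) or `"link"` (logit).
#' @return Numeric vector of d', one per repeat.
#' @export
dprime_by_repeat <- function(result, scale = c("response", "link")) {
  scale <- match.arg(scale)
  sc <- result$scores
  lab <- if ("is_dog" %in% names(sc)) sc$is_dog else sc$is_second
  s <- sc$score
  if (scale == "link") s <- log(s / (1 - s))
  vapply(split(seq_len(nrow(sc)), sc$rep), function(ix) {
    dprime(s[ix][lab[ix] == 0], s[ix][lab[ix] == 1])
  }, 0)
}

#' d' of the two single-region ensembles and their pooled combination
#'
#' @param result_te,result_teo,result_combined `decoding_result`s from the
#'   same strategy with matched repeat structure (equal repeat counts; the
#'   combined run pools equal neuron counts from both regions).
#' @param scale Passed to [dprime_by_repeat()].
#' @return List of class `ensemble_dprimes` with per-repeat vectors `TE`,
#'   `TEO`, `combined`.
#' @export
ensemble_dprimes <- function(result_te, result_teo, result_combined,
                             scale = "response") {
  out <- list(TE = dprime_by_repeat(result_te, scale),
              TEO = dprime_by_repeat(result_teo, scale),
              combined = dprime_by_repeat(result_combined, scale))
  if (length(unique(lengths(out))) != 1) {
    stop("repeat counts differ across ensembles")
  }
  structure(out, class = "ensemble_dprimes")
}

#' Classify how two regions combine their category information
#'
#' Operationalizes the d' taxonomy with two permutation tests on the
#' repeat-level d' values at level `alpha`: combined vs the stronger
#' individual region, and combined vs the per-repeat sum of the two
#' regions. Combined not different from the stronger region: "redundant";
#' significantly below it: "noise_adding"; significantly above it but
#' below the sum: "complementary"; not below the sum: "independent".
#'
#' @param d_te,d_teo,d_combined Per-repeat d' vectors of equal length (or
#'   pass an `ensemble_dprimes` as `d_te`).
#' @param n_perm Permutations per test.
#' @param alpha Test level.
#' @param seed Optional seed.
#' @return List of class `combination_verdict`: `verdict`, `p_max`,
#'   `p_sum`, and the three mean d' values.
#' @export
classify_combination <- function(d_te, d_teo = NULL, d_combined = NULL,
                                 n_perm = 1000, alpha = 0.05, seed = NULL) {
  if (inherits(d_te, "ensemble_dprimes")) {
    d_teo <- d_te$TEO; d_combined <- d_te$combined; d_te <- d_te$TE
  }
  if (length(d_te) != length(d_teo) ||
      length(d_te) != length(d_combined)) {
    stop("repeat counts must match")
  }
  if (!is.null(seed)) set.seed(seed)
  stronger <- if (mean(d_te) >= mean(d_teo)) d_te else d_teo
  d_sum <- d_te + d_teo
  p_max <- permutation_compare(d_combined, stronger, n_perm = n_perm)
  p_sum <- permutation_compare(d_combined, d_sum, n_perm = n_perm)
  verdict <- if (p_max >= alpha) {
    "redundant"
  } else if (mean(d_combined) < mean(stronger)) {
    "noise_adding"
  } else if (p_sum < alpha && mean(d_combined) < mean(d_sum)) {
    "complementary"
  } else {
    "independent"
  }
  structure(list(verdict = verdict, p_max = p_max, p_sum = p_sum,
                 mean_te = mean(d_te), mean_teo = mean(d_teo),
                 mean_combined = mean(d_combined), alpha = alpha),
            class = "combination_verdict")
}

#' @export
print.combination_verdict <- function(x, ...) {
  cat(sprintf(
    "<combination_verdict> %s (d' TE %.2f, TEO %.2f, combined %.2f; p vs max %.3g, p vs sum %.3g)\n",
    x$verdict, x$mean_te, x$mean_teo, x$mean_combined, x$p_max, x$p_sum))
  invisible(x)
}
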