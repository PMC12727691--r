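# Cross-day inference: linear models with region x day interactions,
# bootstrap correlation-difference tests, permutation comparisons, FDR
# correction, behavior-neural association, and psychometric fits.

#' Linear fit of a metric on learning day
#'
#' Least-squares fit `metric ~ day` with day coded 1, 2, 3, ...; a
#' significant positive day coefficient indicates an increase over
#' learning.
#'
#' @param metric Per-observation metric values.
#' @param day Day labels (>= 2 distinct days).
#' @return List of class `learning_fit`: `coefficients` (term, estimate,
#'   p), `aic`, `bic`, and the day-slope `p_slope`/`slope` shortcuts.
#' @export
fit_day_lm <- function(metric, day) {
  if (length(unique(day)) < 2) stop("need at least 2 distinct days")
  fit <- lm(metric ~ day, data = data.frame(metric = metric,
                                            day = as.numeric(day)))
  s <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(s), estimate = s[, 1],
                              p = s[, 4], row.names = NULL),
    slope = s["day", 1], p_slope = s["day", 4],
    aic = AIC(fit), bic = BIC(fit), model = fit),
    class = "learning_fit")
}

#' Region-by-day interaction model
#'
#' Fits `metric ~ region + day + region:day` with region coded 0 for TEO
#' and 1 for TE; a significant interaction coefficient indicates divergent
#' learning patterns in the two regions.
#'
#' @param metric Per-observation metric values.
#' @param region Region labels ("TE"/"TEO").
#' @param day Day labels.
#' @return A `learning_fit` whose `interaction`/`p_interaction` shortcuts
#'   hold the region-by-day term.
#' @export
fit_region_day_interaction <- function(metric, region, day) {
  stopifnot(all(region %in% c("TE", "TEO")))
  if (length(unique(region)) < 2) stop("both regions required")
  if (length(unique(day)) < 2) stop("need at least 2 distinct days")
  d <- data.frame(metric = metric, region = as.numeric(region == "TE"),
                  day = as.numeric(day))
  fit <- lm(metric ~ region * day, data = d)
  s <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(s), estimate = s[, 1],
                              p = s[, 4], row.names = NULL),
    interaction = s["region:day", 1], p_interaction = s["region:day", 4],
    aic = AIC(fit), bic = BIC(fit), model = fit),
    class = "learning_fit")
}

.boot_cor <- function(values_by_day, covariate, n_boot) {
  # bootstrap r(day-mean of resampled values, covariate); day labels are
  # never resampled
  d <- length(values_by_day)
  means <- matrix(0, d, n_boot)
  for (i in seq_len(d)) {
    v <- values_by_day[[i]]
    idx <- matrix(sample.int(length(v), length(v) * n_boot, replace = TRUE),
                  ncol = n_boot)
    means[i, ] <- colMeans(matrix(v[idx], ncol = n_boot))
  }
  xc <- covariate - mean(covariate)
  mc <- means - rep(colMeans(means), each = d)
  num <- colSums(mc * xc)
  den <- sqrt(colSums(mc^2) * sum(xc^2))
  r <- num / den
  r[den == 0] <- 0
  r
}

.boot_ci <- function(delta, level, sided) {
  if (sided == "two") {
    ci <- quantile(delta, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE)
    significant <- ci[1] > 0 || ci[2] < 0
  } else {
    ci <- c(quantile(delta, 1 - level, names = FALSE), Inf)
    significant <- ci[1] > 0
  }
  # bootstrap p: twice the smaller tail of the delta distribution
  p <- 2 * min((1 + sum(delta <= 0)) / (length(delta) + 1),
               (1 + sum(delta >= 0)) / (length(delta) + 1))
  structure(list(ci = ci, level = level, sided = sided,
                 significant = significant, p = min(p, 1),
                 delta_mean = mean(delta),
                 n_boot = length(delta), delta = delta),
            class = "bootstrap_comparison")
}

#' Bootstrap test of metric-vs-day correlation against its shuffled control
#'
#' For each bootstrap sample, the repeat-level values (and, in parallel,
#' the shuffled-control values) are resampled with replacement within each
#' day and averaged per day; the Pearson correlation of these day means
#' against the day number (or another per-day covariate) is computed for
#' both, and the distribution of `r(real) - r(shuffled)` is summarized.
#' The correlation is significant when the CI excludes 0.
#'
#' @param values_by_day List (one element per day) of repeat-level values.
#' @param shuffled_by_day Matching list of shuffled-control values.
#' @param covariate Per-day covariate; defaults to the day numbers
#'   1, 2, 3, ... Use behavioral performance to test behavior-decoding
#'   correlation.
#' @param n_boot Bootstrap samples (default 5000).
#' @param level CI level (default 0.95).
#' @param sided `"two"` or `"one"` (one-tailed lower bound).
#' @param seed Optional seed.
#' @return A `bootstrap_comparison` with `ci`, `significant`,
#'   `delta_mean`.
#' @export
bootstrap_corr_vs_day <- function(values_by_day, shuffled_by_day,
                                  covariate = seq_along(values_by_day),
                                  n_boot = 5000, level = 0.95,
                                  sided = c("two", "one"), seed = NULL) {
  sided <- match.arg(sided)
  stopifnot(length(values_by_day) == length(shuffled_by_day),
            length(covariate) == length(values_by_day))
  if (length(values_by_day) < 3) stop("need at least 3 days")
  if (any(lengths(values_by_day) < 2) || any(lengths(shuffled_by_day) < 2)) {
    stop("need at least 2 values per day")
  }
  if (!is.null(seed)) set.seed(seed)
  r_real <- .boot_cor(values_by_day, covariate, n_boot)
  r_shuf <- .boot_cor(shuffled_by_day, covariate, n_boot)
  .boot_ci(r_real - r_shuf, level, sided)
}

#' Bootstrap comparison of two series' correlations with a common covariate
#'
#' Resamples the observation indices (jointly for both series) with
#' replacement and computes the distribution of
#' `r(series_a, covariate) - r(series_b, covariate)`; used for analyses
#' without repeated measurements (one value per day), e.g. comparing the
#' TE and TEO percentage-vs-day correlations.
#'
#' @param series_a,series_b Observed series (equal length).
#' @param covariate Common covariate (e.g. day numbers).
#' @param n_boot Bootstrap samples.
#' @param level CI level.
#' @param sided `"two"` or `"one"` (lower bound of a one-tailed CI).
#' @param seed Optional seed.
#' @return A `bootstrap_comparison`.
#' @export
bootstrap_corr_difference <- function(series_a, series_b, covariate,
                                      n_boot = 5000, level = 0.95,
                                      sided = c("two", "one"),
                                      seed = NULL) {
  sided <- match.arg(sided)
  n <- length(covariate)
  stopifnot(length(series_a) == n, length(series_b) == n, n >= 3)
  if (!is.null(seed)) set.seed(seed)
  delta <- vapply(seq_len(n_boot), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    if (sd(covariate[ix]) == 0 || sd(series_a[ix]) == 0 ||
        sd(series_b[ix]) == 0) return(0)
    cor(series_a[ix], covariate[ix]) - cor(series_b[ix], covariate[ix])
  }, 0)
  .boot_ci(delta, level, sided)
}

#' Two-sided permutation test for a difference in means
#'
#' Permutes the group labels of the pooled values and compares the
#' absolute mean difference; random permutations use the add-one
#' convention (b + 1)/(n + 1), while `exact = TRUE` enumerates every
#' split.
#'
#' @param dist_a,dist_b Value vectors (e.g. repeat-level accuracies or
#'   d' values of two conditions).
#' @param n_perm Random permutations (ignored when exact).
#' @param exact Enumerate all splits (feasible for small samples)?
#' @param seed Optional seed.
#' @return Two-sided p-value.
#' @export
permutation_compare <- function(dist_a, dist_b, n_perm = 1000,
                                exact = FALSE, seed = NULL) {
  if (length(dist_a) == 0 || length(dist_b) == 0) {
    stop("both distributions must be non-empty")
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- c(dist_a, dist_b)
  n1 <- length(dist_a); n <- length(pool)
  obs <- abs(mean(dist_a) - mean(dist_b))
  tot <- sum(pool)
  stat_from_sum1 <- function(s1) {
    abs(s1 / n1 - (tot - s1) / (n - n1))
  }
  if (exact) {
    if (choose(n, n1) > 2e5) stop("too many splits for exact enumeration")
    s1 <- combn(n, n1, function(ix) sum(pool[ix]))
    return(mean(stat_from_sum1(s1) >= obs - 1e-12))
  }
  perm <- vapply(seq_len(n_perm), function(i) {
    stat_from_sum1(sum(pool[sample.int(n, n1)]))
  }, 0)
  (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotone and capped at 1.
#'
#' @param pvals p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' Regress behavioral performance on decoding accuracy
#'
#' Fits `behavior ~ accuracy + monkey` for the TE, TEO, and TE + TEO
#' predictor sets (monkey identity as a fixed 0/1 covariate), reporting
#' per-predictor slope p-values, AIC and BIC per model, and the
#' lowest-AIC model. An accuracy-by-monkey interaction can be added.
#'
#' @param accuracy_te,accuracy_teo Per-day mean decoding accuracies.
#' @param behavior Per-day behavioral correct rate.
#' @param monkey Per-day subject code (0/1 or a 2-level factor).
#' @param include_interaction Add `accuracy:monkey` to the single-region
#'   models?
#' @return List: `models` (data.frame with slope p, AIC, BIC per model),
#'   `best` (lowest-AIC model name), `fits` (the lm objects).
#' @export
behavior_neural_regression <- function(accuracy_te, accuracy_teo, behavior,
                                       monkey,
                                       include_interaction = FALSE) {
  n <- length(behavior)
  stopifnot(length(accuracy_te) == n, length(accuracy_teo) == n,
            length(monkey) == n)
  monkey <- as.numeric(factor(monkey)) - 1
  d <- data.frame(behavior = behavior, te = accuracy_te,
                  teo = accuracy_teo, monkey = monkey)
  forms <- list(
    TE = if (include_interaction) behavior ~ te * monkey else
      behavior ~ te + monkey,
    TEO = if (include_interaction) behavior ~ teo * monkey else
      behavior ~ teo + monkey,
    `TE+TEO` = behavior ~ te + teo + monkey)
  fits <- lapply(forms, lm, data = d)
  slope_p <- function(fit, term) {
    s <- summary(fit)$coefficients
    if (term %in% rownames(s)) s[term, 4] else NA_real_
  }
  models <- data.frame(
    model = names(fits),
    p_te = vapply(fits, slope_p, 0, term = "te"),
    p_teo = vapply(fits, slope_p, 0, term = "teo"),
    aic = vapply(fits, AIC, 0),
    bic = vapply(fits, BIC, 0),
    row.names = NULL)
  list(models = models, best = models$model[which.min(models$aic)],
       fits = fits)
}

#' Pearson partial correlation
#'
#' Correlation of `x` and `y` after linearly removing the covariates from
#' both; the p-value uses the t transform with n - k - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariates Vector, matrix or data.frame of covariates.
#' @return List: `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates) {
  z <- as.matrix(covariates)
  n <- length(x)
  stopifnot(length(y) == n, nrow(z) == n)
  k <- ncol(z)
  if (n <= k + 2) stop("need n > number of covariates + 2")
  rx <- stats::residuals(lm(x ~ z))
  ry <- stats::residuals(lm(y ~ z))
  r <- cor(rx, ry)
  df <- n - k - 2
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df), df = df)
}

#' Maximum-likelihood psychometric fit
#'
#' Fits P(dog choice) = logistic(slope * (level - 50)/50 + bias) by
#' binomial maximum likelihood. For separable data the slope is capped.
#'
#' @param choice_dog 0/1 indicator of the dog (second-interval) choice per
#'   trial.
#' @param morph_level Per-trial morph level.
#' @param slope_cap Absolute cap on the fitted slope (default 50).
#' @return List: `slope`, `bias`, `capped`.
#' @export
fit_psychometric <- function(choice_dog, morph_level, slope_cap = 50) {
  stopifnot(length(choice_dog) == length(morph_level),
            all(choice_dog %in% c(0, 1)))
  if (length(unique(morph_level)) < 3) {
    stop("need choices at >= 3 morph levels")
  }
  x <- (morph_level - 50) / 50
  fit <- suppressWarnings(glm(choice_dog ~ x, family = binomial()))
  slope <- unname(coef(fit)["x"])
  capped <- abs(slope) > slope_cap
  if (capped) slope <- sign(slope) * slope_cap
  list(slope = slope, bias = unname(coef(fit)["(Intercept)"]),
       capped = capped)
}
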