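# Per-neuron statistics: nested ANOVA with omega-squared effect size,
# ROC category preference with a permutation null, selectivity
# classification, and choice probability on boundary trials.

#' Nested ANOVA on a neuron's trial rates
#'
#' Fits the fixed-effects ANOVA with factors category, morph identity, and
#' morph level nested within category (sequential sums of squares), plus
#' selectable two-way interactions. Boundary (50% morph) trials are
#' excluded before fitting.
#'
#' @param rate Per-trial response rates.
#' @param category,morph_level,morph_identity Per-trial stimulus labels
#'   (category is derived from `morph_level` when omitted).
#' @param interactions Character vector among `"category:identity"` and
#'   `"category:identity:level"` (morph identity crossed with level within
#'   category).
#' @return List of class `anova_result` with `table` (per-factor SSQ, df,
#'   F, p and omega-squared), `ms_error`, `df_error` and `ssq_total` (total
#'   corrected sum of squares).
#' @seealso [omega_squared()], [category_effect_size()]
#' @export
nested_anova <- function(rate, morph_level, morph_identity,
                         category = assign_category(morph_level),
                         interactions = "category:identity") {
  keep <- morph_level != 50
  rate <- rate[keep]
  category <- category[keep]
  morph_level <- morph_level[keep]
  morph_identity <- morph_identity[keep]
  d <- data.frame(y = rate, category = factor(category),
                  identity = factor(morph_identity),
                  level = factor(morph_level))
  cell <- interaction(d$identity, d$level, drop = TRUE)
  small <- names(which(table(cell) < 2))
  if (length(small) > 0) {
    stop("cell(s) with fewer than 2 trials (identity.level): ",
         paste(head(small, 5), collapse = ", "))
  }
  bad <- setdiff(interactions, c("category:identity",
                                 "category:identity:level"))
  if (length(bad) > 0) stop("unknown interaction term(s): ",
                            paste(bad, collapse = ", "))
  rhs <- c("category", "identity", "category:level")
  if ("category:identity" %in% interactions) {
    rhs <- c(rhs, "category:identity")
  }
  if ("category:identity:level" %in% interactions) {
    rhs <- c(rhs, "category:identity:level")
  }
  fit <- aov(stats::as.formula(paste("y ~", paste(rhs, collapse = " + "))),
             data = d)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  res_i <- which(rn == "Residuals")
  if (tab[res_i, "Df"] < 1) stop("no residual degrees of freedom")
  ms_error <- tab[res_i, "Mean Sq"]
  ssq_total <- sum(tab[, "Sum Sq"])
  eff <- setdiff(seq_len(nrow(tab)), res_i)
  out <- data.frame(
    factor = rn[eff],
    ssq = tab[eff, "Sum Sq"],
    df = tab[eff, "Df"],
    f = tab[eff, "F value"],
    p = tab[eff, "Pr(>F)"],
    stringsAsFactors = FALSE)
  out$omega_squared <- vapply(seq_len(nrow(out)), function(i) {
    omega_squared(out$ssq[i], out$df[i], ms_error, ssq_total)
  }, 0)
  structure(list(table = out, ms_error = ms_error,
                 df_error = tab[res_i, "Df"], ssq_total = ssq_total),
            class = "anova_result")
}

#' Omega-squared effect size
#'
#' Bias-corrected proportion of variance attributable to a factor:
#' `(SSQ_effect - df_effect * MS_error) / (SSQ_total + MS_error)`,
#' ranging from -1 to 1.
#'
#' @param ssq_effect Sum of squares of the factor.
#' @param df_effect Its degrees of freedom.
#' @param ms_error Mean squared error.
#' @param ssq_total Total sum of squares.
#' @return Omega-squared.
#' @export
omega_squared <- function(ssq_effect, df_effect, ms_error, ssq_total) {
  den <- ssq_total + ms_error
  if (den <= 0) stop("ssq_total + ms_error must be positive")
  (ssq_effect - df_effect * ms_error) / den
}

#' One-way category effect size
#'
#' Omega-squared of the category factor from a one-way ANOVA of rate on
#' category (the pipeline's default effect-size path; significance comes
#' from the nested model).
#'
#' @param rate Per-trial rates.
#' @param category Per-trial category labels ("cat"/"dog"); boundary trials
#'   must already be excluded.
#' @return Omega-squared of category.
#' @export
category_effect_size <- function(rate, category) {
  stopifnot(all(category %in% c("cat", "dog")))
  tab <- summary(aov(rate ~ factor(category)))[[1]]
  omega_squared(tab[1, "Sum Sq"], tab[1, "Df"], tab[2, "Mean Sq"],
                sum(tab[, "Sum Sq"]))
}

#' ROC area under the curve (dog as positive class)
#'
#' Threshold-sweep AUC, equal to the Mann--Whitney statistic
#' U / (n_dog * n_cat) with ties counted one half.
#'
#' @param rates_dog,rates_cat Rates on dog-like and cat-like trials.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(rates_dog, rates_cat) {
  n1 <- length(rates_dog); n2 <- length(rates_cat)
  if (n1 == 0 || n2 == 0) stop("both rate lists must be non-empty")
  r <- rank(c(rates_dog, rates_cat))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Permutation significance of a category AUC
#'
#' Computes the AUC (dog positive) for one morph identity's trials, builds
#' a Gaussian null by shuffling category labels `n_perm` times and taking
#' the sample mean and SD of the permuted AUCs, and flags the AUC as
#' significant when it falls outside `[mu - 1.96 sigma, mu + 1.96 sigma]`.
#' A significant AUC above the band marks a dog-preferring response, below
#' the band a cat-preferring one.
#'
#' @param rates Per-trial rates for one neuron and one morph identity.
#' @param labels Per-trial category labels ("cat"/"dog").
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional seed.
#' @param neuron_id,morph_identity Carried through into the record.
#' @return List of class `auc_record`: `auc`, `null_mu`, `null_sigma`,
#'   `significant`, `preferred` ("dog"/"cat"/"none").
#' @export
auc_significance <- function(rates, labels, n_perm = 1000, seed = NULL,
                             neuron_id = NA_character_,
                             morph_identity = NA_integer_) {
  stopifnot(length(rates) == length(labels),
            all(labels %in% c("cat", "dog")))
  if (!all(c("cat", "dog") %in% labels)) {
    stop("both category labels must be present")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(rates)
  n1 <- sum(labels == "dog")
  r <- rank(rates)
  base <- n1 * (n1 + 1) / 2
  denom <- n1 * (n - n1)
  auc <- (sum(r[labels == "dog"]) - base) / denom
  perm <- vapply(seq_len(n_perm), function(i) {
    (sum(r[sample.int(n, n1)]) - base) / denom
  }, 0)
  mu <- mean(perm)
  sigma <- sd(perm)
  if (sigma == 0) {
    warning("degenerate permutation null (sigma = 0); flagged not significant")
    sig <- FALSE
  } else {
    sig <- auc < mu - 1.96 * sigma || auc > mu + 1.96 * sigma
  }
  preferred <- if (!sig) "none" else if (auc > mu) "dog" else "cat"
  structure(list(neuron_id = neuron_id, morph_identity = morph_identity,
                 auc = auc, null_mu = mu, null_sigma = sigma,
                 significant = sig, preferred = preferred, n_perm = n_perm),
            class = "auc_record")
}

#' Classify a neuron's category selectivity across morph identities
#'
#' A neuron with at least one significant AUC, all of whose significant
#' AUCs share one preferred category, is "category-selective"; one with
#' significant AUCs of both preferences is "mixed-selectivity"; otherwise
#' "none".
#'
#' @param records List of `auc_record` (or a data.frame with `significant`
#'   and `preferred` columns), one per morph identity.
#' @return `"category_selective"`, `"mixed_selectivity"` or `"none"`.
#' @export
classify_selectivity <- function(records) {
  if (is.data.frame(records)) {
    sig <- records$significant
    pref <- records$preferred
  } else {
    sig <- vapply(records, `[[`, TRUE, "significant")
    pref <- vapply(records, `[[`, "", "preferred")
  }
  pref <- pref[sig]
  if (length(pref) == 0) return("none")
  if (length(unique(pref)) == 1) "category_selective" else "mixed_selectivity"
}

#' Fold an AUC for cat-preferring responses
#'
#' Significant encoding of cat-like images is quantified as `1 - AUC`, so
#' dog- and cat-preferring strengths live on the same scale.
#'
#' @param auc AUC in \[0, 1\].
#' @return `1 - auc`.
#' @export
cat_auc_transform <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  1 - auc
}

#' Choice probability of a neuron on ambiguous trials
#'
#' ROC analysis with trials grouped by the animal's choice (second-interval
#' release as the positive class), folded so values >= 0.5 measure choice
#' discrimination regardless of direction; intended for boundary-image
#' trials. Significance is a permutation test shuffling choice labels, with
#' each permuted AUC folded the same way so the null respects the folding.
#'
#' @param rates Per-trial rates.
#' @param choices Per-trial choices ("first_interval"/"second_interval").
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @param alpha Significance level (default 0.05).
#' @return List: `auc` (raw), `folded_auc` (>= 0.5), `p` (add-one
#'   permutation p-value), `significant`.
#' @export
choice_probability <- function(rates, choices, n_perm = 1000, seed = NULL,
                               alpha = 0.05) {
  stopifnot(length(rates) == length(choices),
            all(choices %in% c("first_interval", "second_interval")))
  if (length(unique(choices)) < 2) {
    stop("both choices must be present")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(rates)
  n1 <- sum(choices == "second_interval")
  r <- rank(rates)
  base <- n1 * (n1 + 1) / 2
  denom <- n1 * (n - n1)
  auc <- (sum(r[choices == "second_interval"]) - base) / denom
  folded <- max(auc, 1 - auc)
  perm <- vapply(seq_len(n_perm), function(i) {
    a <- (sum(r[sample.int(n, n1)]) - base) / denom
    max(a, 1 - a)
  }, 0)
  p <- (1 + sum(perm >= folded)) / (n_perm + 1)
  list(auc = auc, folded_auc = folded, p = p, significant = p < alpha,
       n_perm = n_perm)
}

#' Per-neuron summary statistics for one session
#'
#' Runs the nested ANOVA (category significance) and the one-way category
#' effect size for every neuron in the session; optionally also the
#' per-identity AUC records and the selectivity label.
#'
#' @param session A `neural_session`.
#' @param alpha Significance level for the category factor.
#' @param include_auc Also run [auc_significance()] per morph identity (and
#'   classify selectivity)? Slower.
#' @param n_perm Permutations per AUC when `include_auc`.
#' @param seed Optional seed (AUC permutations).
#' @param interactions Passed to [nested_anova()].
#' @return data.frame with one row per neuron: `neuron_id`, `region`,
#'   `day`, `p_category`, `omega_category`, `category_significant`, and
#'   when `include_auc` also `n_sig_dog_auc`, `n_sig_cat_auc`,
#'   `selectivity`. When `include_auc`, the full AUC-record table is
#'   attached as attribute `"auc_records"`.
#' @export
single_unit_summary <- function(session, alpha = 0.05, include_auc = FALSE,
                                n_perm = 1000, seed = NULL,
                                interactions = "category:identity") {
  validate_session(session)
  if (!is.null(seed)) set.seed(seed)
  t <- session$trials
  keep <- t$morph_level != 50
  lev <- t$morph_level[keep]
  idd <- t$morph_identity[keep]
  catg <- assign_category(lev)
  rates <- session$counts[keep, , drop = FALSE] / session$window_s
  n <- nrow(session$neurons)
  p_cat <- omega <- numeric(n)
  for (j in seq_len(n)) {
    a <- nested_anova(rates[, j], lev, idd, catg, interactions = interactions)
    p_cat[j] <- a$table$p[a$table$factor == "category"]
    omega[j] <- category_effect_size(rates[, j], catg)
  }
  out <- data.frame(neuron_id = session$neurons$neuron_id,
                    region = session$neurons$region,
                    day = session$day,
                    p_category = p_cat, omega_category = omega,
                    category_significant = p_cat < alpha,
                    stringsAsFactors = FALSE)
  if (include_auc) {
    recs <- list()
    n_dog <- n_cat <- integer(n)
    selectivity <- character(n)
    for (j in seq_len(n)) {
      rj <- lapply(sort(unique(idd)), function(id) {
        m <- idd == id
        auc_significance(rates[m, j], catg[m], n_perm = n_perm,
                         neuron_id = session$neurons$neuron_id[j],
                         morph_identity = id)
      })
      pref <- vapply(rj, `[[`, "", "preferred")
      n_dog[j] <- sum(pref == "dog")
      n_cat[j] <- sum(pref == "cat")
      selectivity[j] <- classify_selectivity(rj)
      recs <- c(recs, rj)
    }
    out$n_sig_dog_auc <- n_dog
    out$n_sig_cat_auc <- n_cat
    out$selectivity <- selectivity
    attr(out, "auc_records") <- do.call(rbind, lapply(recs, function(r) {
      data.frame(neuron_id = r$neuron_id, morph_identity = r$morph_identity,
                 auc = r$auc, null_mu = r$null_mu, null_sigma = r$null_sigma,
                 significant = r$significant, preferred = r$preferred,
                 stringsAsFactors = FALSE)
    }))
  }
  out
}
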