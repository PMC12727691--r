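# Population decoding drivers. Every strategy runs its shuffled control
# inside the same repeat with identical neuron and trial draws, differing
# only in the permuted training labels, so real and control accuracies are
# paired draw-for-draw.

.region_counts <- function(session, region, include_boundary = FALSE) {
  if (region == "combined") {
    te <- build_population_matrix(session, "TE", include_boundary)
    teo <- build_population_matrix(session, "TEO", include_boundary)
    list(mats = list(TE = te$counts, TEO = teo$counts), trials = te$trials)
  } else {
    pm <- build_population_matrix(session, region, include_boundary)
    list(mats = list(pm$counts), trials = pm$trials)
  }
}

.draw_neuron_columns <- function(mats, n_neurons) {
  # combined ensembles pool equal neuron counts from both regions
  cols <- lapply(mats, function(m) {
    if (ncol(m) < n_neurons) {
      stop("region has only ", ncol(m), " neurons; ", n_neurons,
           " requested")
    }
    sample.int(ncol(m), n_neurons)
  })
  do.call(cbind, Map(function(m, cc) m[, cc, drop = FALSE], mats, cols))
}

.new_decoding_result <- function(strategy, region, acc, acc_shuf, scores,
                                 params, diagnostics = NULL) {
  structure(list(strategy = strategy, region = region,
                 accuracy = acc, accuracy_shuffled = acc_shuf,
                 scores = scores, params = params,
                 diagnostics = diagnostics),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %s, %s: mean accuracy %.3f (shuffled %.3f), %d repeats\n",
    x$strategy, x$region, mean(x$accuracy), mean(x$accuracy_shuffled),
    length(x$accuracy)))
  invisible(x)
}

#' Traditional category decoding
#'
#' For each repeat: a fresh subsample of `n_neurons` neurons and, for every
#' non-boundary image, `trials_per_image` freshly drawn trials split into
#' train/validation/test sets per image; responses are z-scored per neuron,
#' the read-out is trained with early stopping on the validation set, and
#' accuracy is the fraction of test trials classified into the correct
#' category. The paired shuffled control permutes training labels only.
#'
#' @param session A `neural_session`.
#' @param region `"TE"`, `"TEO"` or `"combined"` (equal neuron counts
#'   pooled from both regions).
#' @param n_neurons Neurons subsampled per repeat (per region when
#'   combined).
#' @param trials_per_image Trials drawn per image (without replacement;
#'   errors if any image has fewer).
#' @param split Named counts `c(train=, val=, test=)` summing to
#'   `trials_per_image`.
#' @param n_repeats Decoding repeats.
#' @param seed Optional seed.
#' @param spec A [decoder_spec()].
#' @param zscore_scope `"all"` fits the z-scoring on the full per-repeat
#'   trial draw (train+validation+test); `"train"` is the leakage-free
#'   variant recommended for new studies.
#' @param diagnostics Keep per-repeat split bookkeeping (role of every
#'   drawn trial)?
#' @return A `decoding_result` with per-repeat `accuracy`,
#'   `accuracy_shuffled`, and per-test-trial `scores` (sigmoid outputs with
#'   true labels).
#' @export
decode_traditional <- function(session, region, n_neurons,
                               trials_per_image = 6,
                               split = c(train = trials_per_image - 2,
                                         val = 1, test = 1),
                               n_repeats = 100, seed = NULL,
                               spec = decoder_spec(),
                               zscore_scope = c("all", "train"),
                               diagnostics = FALSE) {
  zscore_scope <- match.arg(zscore_scope)
  stopifnot(sum(split) == trials_per_image, all(split >= 1))
  if (!is.null(seed)) set.seed(seed)
  rc <- .region_counts(session, region)
  trials <- rc$trials
  key <- paste(trials$morph_identity, trials$morph_level)
  idx_by_image <- split(seq_len(nrow(trials)), key)
  deficient <- names(which(lengths(idx_by_image) < trials_per_image))
  if (length(deficient) > 0) {
    stop("image(s) with fewer than ", trials_per_image, " trials: ",
         paste(deficient, collapse = "; "))
  }
  is_dog <- as.integer(trials$morph_level > 50)
  roles <- rep(c("train", "val", "test"), split[c("train", "val", "test")])

  acc <- acc_shuf <- numeric(n_repeats)
  scores <- vector("list", n_repeats)
  diag <- if (diagnostics) vector("list", n_repeats) else NULL
  for (r in seq_len(n_repeats)) {
    x_all <- .draw_neuron_columns(rc$mats, n_neurons)
    sel <- unlist(lapply(idx_by_image, function(ix) {
      ix[sample.int(length(ix), trials_per_image)]
    }), use.names = FALSE)
    role <- rep(roles, length(idx_by_image))
    x <- x_all[sel, , drop = FALSE]
    if (zscore_scope == "all") x <- suppressWarnings(zscore_per_neuron(x))
    y <- is_dog[sel]
    tr <- role == "train"; va <- role == "val"; te <- role == "test"
    if (zscore_scope == "train") {
      mu <- colMeans(x[tr, , drop = FALSE])
      s <- apply(x[tr, , drop = FALSE], 2, sd)
      s[s == 0] <- 1
      x <- sweep(sweep(x, 2, mu), 2, s, "/")
    }
    fit <- train_decoder(x[tr, ], y[tr], x[va, ], y[va], spec)
    sc <- predict(fit, x[te, ])
    acc[r] <- mean((sc > 0.5) == (y[te] == 1))
    fit_s <- train_decoder(x[tr, ], sample(y[tr]), x[va, ], y[va], spec)
    sc_s <- predict(fit_s, x[te, ])
    acc_shuf[r] <- mean((sc_s > 0.5) == (y[te] == 1))
    scores[[r]] <- data.frame(rep = r, score = sc, is_dog = y[te])
    if (diagnostics) diag[[r]] <- data.frame(trial_row = sel, role = role)
  }
  .new_decoding_result("traditional", region, acc, acc_shuf,
                       do.call(rbind, scores),
                       list(n_neurons = n_neurons,
                            trials_per_image = trials_per_image,
                            split = split, zscore_scope = zscore_scope,
                            seed = seed),
                       diag)
}

#' Generalization category decoding (leave-morph-identities-out)
#'
#' Cross-validation folds partition the morph identities; the read-out is
#' trained on trials from the other identities' images and tested on
#' never-before-seen images from the held-out identities. Per repeat, the
#' full k-fold pass runs on one fresh neuron subsample, and accuracy pools
#' all held-out-identity test trials. In the shuffled control the category
#' labels of training (and, by default, validation) trials are permuted
#' while test labels are unchanged.
#'
#' @inheritParams decode_traditional
#' @param n_train Training trials per image (the remaining
#'   `trials_per_image - n_train` are validation).
#' @param n_folds Number of identity folds; must divide `n_identities`.
#' @param shuffle_validation Permute validation labels together with
#'   training labels in the control (default `TRUE` for this strategy)?
#' @return A `decoding_result`.
#' @export
decode_generalization <- function(session, region, n_neurons,
                                  trials_per_image = 6,
                                  n_train = trials_per_image - 1,
                                  n_folds = 10, n_repeats = 100,
                                  seed = NULL, spec = decoder_spec(),
                                  shuffle_validation = TRUE,
                                  diagnostics = FALSE) {
  stopifnot(n_train >= 1, n_train < trials_per_image)
  if (!is.null(seed)) set.seed(seed)
  rc <- .region_counts(session, region)
  trials <- rc$trials
  identities <- sort(unique(trials$morph_identity))
  if (length(identities) %% n_folds != 0) {
    stop("number of identities (", length(identities),
         ") not divisible into ", n_folds, " folds")
  }
  key <- paste(trials$morph_identity, trials$morph_level)
  idx_by_image <- split(seq_len(nrow(trials)), key)
  deficient <- names(which(lengths(idx_by_image) < trials_per_image))
  if (length(deficient) > 0) {
    stop("image(s) with fewer than ", trials_per_image, " trials: ",
         paste(deficient, collapse = "; "))
  }
  image_identity <- as.integer(vapply(strsplit(names(idx_by_image), " "),
                                      `[`, "", 1))
  is_dog <- as.integer(trials$morph_level > 50)
  per_fold <- length(identities) / n_folds

  acc <- acc_shuf <- numeric(n_repeats)
  scores <- vector("list", n_repeats)
  diag <- if (diagnostics) vector("list", n_repeats) else NULL
  for (r in seq_len(n_repeats)) {
    x_all <- .draw_neuron_columns(rc$mats, n_neurons)
    fold_of <- setNames(rep(seq_len(n_folds), each = per_fold)[
      order(sample(length(identities)))], identities)
    ok <- ok_s <- tot <- 0
    rep_scores <- list()
    for (f in seq_len(n_folds)) {
      held <- image_identity %in% identities[fold_of == f]
      sel_tr <- sel_va <- sel_te <- integer(0)
      for (i in which(!held)) {
        ix <- idx_by_image[[i]]
        draw <- ix[sample.int(length(ix), trials_per_image)]
        sel_tr <- c(sel_tr, draw[seq_len(n_train)])
        sel_va <- c(sel_va, draw[(n_train + 1):trials_per_image])
      }
      for (i in which(held)) {
        ix <- idx_by_image[[i]]
        sel_te <- c(sel_te, ix[sample.int(length(ix), trials_per_image)])
      }
      sel <- c(sel_tr, sel_va, sel_te)
      x <- suppressWarnings(zscore_per_neuron(x_all[sel, , drop = FALSE]))
      y <- is_dog[sel]
      n_tr <- length(sel_tr); n_va <- length(sel_va)
      tr <- seq_len(n_tr); va <- n_tr + seq_len(n_va)
      te <- (n_tr + n_va + 1):length(sel)
      fit <- train_decoder(x[tr, ], y[tr], x[va, ], y[va], spec)
      sc <- predict(fit, x[te, ])
      ok <- ok + sum((sc > 0.5) == (y[te] == 1))
      y_shuf <- y
      pool <- if (shuffle_validation) c(tr, va) else tr
      y_shuf[pool] <- sample(y[pool])
      fit_s <- train_decoder(x[tr, ], y_shuf[tr], x[va, ], y_shuf[va], spec)
      sc_s <- predict(fit_s, x[te, ])
      ok_s <- ok_s + sum((sc_s > 0.5) == (y[te] == 1))
      tot <- tot + length(te)
      rep_scores[[f]] <- data.frame(rep = r, fold = f, score = sc,
                                    is_dog = y[te])
    }
    acc[r] <- ok / tot
    acc_shuf[r] <- ok_s / tot
    scores[[r]] <- do.call(rbind, rep_scores)
    if (diagnostics) diag[[r]] <- fold_of
  }
  .new_decoding_result("generalization", region, acc, acc_shuf,
                       do.call(rbind, scores),
                       list(n_neurons = n_neurons,
                            trials_per_image = trials_per_image,
                            n_train = n_train, n_folds = n_folds,
                            shuffle_validation = shuffle_validation,
                            seed = seed),
                       diag)
}

#' Choice decoding on boundary-image trials
#'
#' Trials of the 50% morph images are grouped by the animal's choice
#' (regardless of image identity) and, per choice group, randomly divided
#' into training (80%), validation (10%) and test (10%) sets; fractional
#' sizes round down for validation/test with the remainder going to
#' training, and at least one trial is forced into each part. The shuffled
#' control permutes training labels.
#'
#' @inheritParams decode_traditional
#' @param n_neurons Neurons subsampled per repeat; `NULL` uses the whole
#'   region.
#' @return A `decoding_result` (positive class = second-interval choice).
#' @export
decode_choice <- function(session, region, n_neurons = NULL,
                          n_repeats = 500, seed = NULL,
                          spec = decoder_spec()) {
  if (!is.null(seed)) set.seed(seed)
  rc <- .region_counts(session, region, include_boundary = TRUE)
  trials <- rc$trials
  keep <- trials$morph_level == 50 &
    trials$choice %in% c("first_interval", "second_interval")
  if (sum(keep) == 0) stop("no boundary-image trials with a choice")
  trials <- trials[keep, , drop = FALSE]
  mats <- lapply(rc$mats, function(m) m[keep, , drop = FALSE])
  y_all <- as.integer(trials$choice == "second_interval")
  if (length(unique(y_all)) < 2) stop("both choices must be present")
  groups <- split(seq_along(y_all), y_all)
  sizes <- lapply(groups, function(g) {
    n <- length(g)
    n_va <- max(1L, floor(0.1 * n)); n_te <- max(1L, floor(0.1 * n))
    n_tr <- n - n_va - n_te
    if (n_tr < 1) stop("too few trials in a choice group (", n, ")")
    c(train = n_tr, val = n_va, test = n_te)
  })
  if (is.null(n_neurons)) n_neurons <- min(vapply(rc$mats, ncol, 0L))

  acc <- acc_shuf <- numeric(n_repeats)
  scores <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    x_all <- .draw_neuron_columns(mats, n_neurons)
    role <- character(length(y_all))
    for (g in seq_along(groups)) {
      ord <- groups[[g]][sample.int(length(groups[[g]]))]
      sz <- sizes[[g]]
      role[ord] <- rep(c("train", "val", "test"), sz)
    }
    x <- suppressWarnings(zscore_per_neuron(x_all))
    tr <- role == "train"; va <- role == "val"; te <- role == "test"
    fit <- train_decoder(x[tr, ], y_all[tr], x[va, ], y_all[va], spec)
    sc <- predict(fit, x[te, , drop = FALSE])
    acc[r] <- mean((sc > 0.5) == (y_all[te] == 1))
    fit_s <- train_decoder(x[tr, ], sample(y_all[tr]), x[va, ], y_all[va],
                           spec)
    sc_s <- predict(fit_s, x[te, , drop = FALSE])
    acc_shuf[r] <- mean((sc_s > 0.5) == (y_all[te] == 1))
    scores[[r]] <- data.frame(rep = r, score = sc, is_second = y_all[te])
  }
  .new_decoding_result("choice", region, acc, acc_shuf,
                       do.call(rbind, scores),
                       list(n_neurons = n_neurons, seed = seed), NULL)
}

#' Category decoding tested separately on correct and error trials
#'
#' Training uses only correct trials from the low-ambiguity images (morph
#' levels 0, 25, 75, 100); an image is excluded from all days if it lacks
#' `min_correct` correct trials in any qualifying day, and its category
#' partner (0 vs 100, 25 vs 75, same identity) is excluded with it to keep
#' training balanced. Only days with behavioral performance of at least
#' `min_performance` qualify. Testing uses the ambiguous images (levels 35,
#' 40, 45, 55, 60, 65) having both correct and error trials, excluded
#' day-locally. Per repeat, one decoder is trained on the day's sampled
#' correct trials and evaluated separately on ambiguous correct and
#' ambiguous error trials; paired shuffled controls permute training
#' labels.
#'
#' @param sessions List of `neural_session`, one per day.
#' @inheritParams decode_traditional
#' @param min_correct Correct trials sampled per training image (an extra
#'   correct trial per image feeds the validation set where available).
#' @param min_performance Day-qualification threshold on
#'   [behavioral_correct_rate()].
#' @return List of class `correct_error_result`: `per_day` (per qualifying
#'   day: per-repeat `accuracy_correct`, `accuracy_error` and their
#'   shuffled controls), `days` (performance/qualification table) and
#'   `exclusions` (the exclusion ledger).
#' @export
decode_correct_vs_error <- function(sessions, region, n_neurons,
                                    min_correct = 3, n_repeats = 200,
                                    min_performance = 0.75, seed = NULL,
                                    spec = decoder_spec()) {
  if (!is.null(seed)) set.seed(seed)
  train_levels <- c(0, 25, 75, 100)
  ambig_levels <- c(35, 40, 45, 55, 60, 65)
  partner <- c("0" = 100, "25" = 75, "75" = 25, "100" = 0)
  perf <- vapply(sessions, behavioral_correct_rate, 0)
  days <- vapply(sessions, `[[`, 0L, "day")
  qual <- perf >= min_performance
  excl <- list()
  day_tab <- data.frame(day = days, performance = perf, qualifying = qual)
  for (d in which(!qual)) {
    excl[[length(excl) + 1]] <- data.frame(
      day = days[d], morph_identity = NA, morph_level = NA,
      reason = "day_below_performance")
  }
  if (!any(qual)) stop("no qualifying days (performance >= ",
                       min_performance, ")")

  stim <- sessions[[which(qual)[1]]]$stimulus_set
  tr_imgs <- stim[stim$morph_level %in% train_levels, , drop = FALSE]
  keep_img <- rep(TRUE, nrow(tr_imgs))
  ikey <- paste(tr_imgs$morph_identity, tr_imgs$morph_level)
  for (d in which(qual)) {
    t <- sessions[[d]]$trials
    for (i in seq_len(nrow(tr_imgs))) {
      n_ok <- sum(t$morph_identity == tr_imgs$morph_identity[i] &
                  t$morph_level == tr_imgs$morph_level[i] &
                  t$outcome == "correct")
      if (n_ok < min_correct && keep_img[i]) {
        keep_img[i] <- FALSE
        excl[[length(excl) + 1]] <- data.frame(
          day = days[d], morph_identity = tr_imgs$morph_identity[i],
          morph_level = tr_imgs$morph_level[i],
          reason = "insufficient_correct_trials")
      }
    }
  }
  # category-balance rule: drop the partner of every dropped image
  for (i in which(!keep_img)) {
    pk <- paste(tr_imgs$morph_identity[i],
                partner[as.character(tr_imgs$morph_level[i])])
    j <- which(ikey == pk)
    if (keep_img[j]) {
      keep_img[j] <- FALSE
      excl[[length(excl) + 1]] <- data.frame(
        day = NA, morph_identity = tr_imgs$morph_identity[j],
        morph_level = tr_imgs$morph_level[j], reason = "partner_excluded")
    }
  }
  tr_imgs <- tr_imgs[keep_img, , drop = FALSE]
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(day = integer(), morph_identity = integer(),
               morph_level = integer(), reason = character())
  if (nrow(tr_imgs) == 0 || length(unique(tr_imgs$category)) < 2) {
    stop("no balanced training images remain; exclusion ledger:\n",
         paste(utils::capture.output(print(exclusions)), collapse = "\n"))
  }

  per_day <- list()
  for (d in which(qual)) {
    s <- sessions[[d]]
    rc <- .region_counts(s, region, include_boundary = TRUE)
    t <- rc$trials
    # day-local test-image qualification
    amb <- stim[stim$morph_level %in% ambig_levels, , drop = FALSE]
    test_imgs <- amb[vapply(seq_len(nrow(amb)), function(i) {
      m <- t$morph_identity == amb$morph_identity[i] &
        t$morph_level == amb$morph_level[i]
      any(m & t$outcome == "correct") && any(m & t$outcome == "error")
    }, TRUE), , drop = FALSE]
    if (nrow(test_imgs) == 0) {
      exclusions <- rbind(exclusions, data.frame(
        day = days[d], morph_identity = NA, morph_level = NA,
        reason = "no_valid_ambiguous_images"))
      next
    }
    tkey <- paste(t$morph_identity, t$morph_level)
    corr_by_img <- lapply(seq_len(nrow(tr_imgs)), function(i) {
      which(tkey == paste(tr_imgs$morph_identity[i],
                          tr_imgs$morph_level[i]) & t$outcome == "correct")
    })
    test_key <- paste(test_imgs$morph_identity, test_imgs$morph_level)
    te_ok <- which(tkey %in% test_key & t$outcome == "correct")
    te_err <- which(tkey %in% test_key & t$outcome == "error")
    y_all <- as.integer(t$morph_level > 50)
    ac <- ae <- ac_s <- ae_s <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      x_all <- .draw_neuron_columns(rc$mats, n_neurons)
      sel_tr <- sel_va <- integer(0)
      for (ix in corr_by_img) {
        k <- min(length(ix), min_correct + 1)
        draw <- ix[sample.int(length(ix), k)]
        sel_tr <- c(sel_tr, draw[seq_len(min(min_correct, length(draw)))])
        if (k > min_correct) sel_va <- c(sel_va, draw[k])
      }
      if (length(sel_va) == 0) sel_va <- sel_tr
      sel <- c(sel_tr, sel_va, te_ok, te_err)
      x <- suppressWarnings(zscore_per_neuron(x_all[sel, , drop = FALSE]))
      y <- y_all[sel]
      n1 <- length(sel_tr); n2 <- length(sel_va)
      tr <- seq_len(n1); va <- n1 + seq_len(n2)
      i_ok <- n1 + n2 + seq_along(te_ok)
      i_err <- n1 + n2 + length(te_ok) + seq_along(te_err)
      fit <- train_decoder(x[tr, ], y[tr], x[va, , drop = FALSE], y[va],
                           spec)
      sc_ok <- predict(fit, x[i_ok, , drop = FALSE])
      sc_err <- predict(fit, x[i_err, , drop = FALSE])
      ac[r] <- mean((sc_ok > 0.5) == (y[i_ok] == 1))
      ae[r] <- mean((sc_err > 0.5) == (y[i_err] == 1))
      fit_s <- train_decoder(x[tr, ], sample(y[tr]),
                             x[va, , drop = FALSE], y[va], spec)
      ac_s[r] <- mean((predict(fit_s, x[i_ok, , drop = FALSE]) > 0.5) ==
                        (y[i_ok] == 1))
      ae_s[r] <- mean((predict(fit_s, x[i_err, , drop = FALSE]) > 0.5) ==
                        (y[i_err] == 1))
    }
    per_day[[as.character(days[d])]] <- list(
      day = days[d], n_test_images = nrow(test_imgs),
      accuracy_correct = ac, accuracy_error = ae,
      accuracy_correct_shuffled = ac_s, accuracy_error_shuffled = ae_s)
  }
  if (length(per_day) == 0) {
    stop("no qualifying test images on any day; exclusion ledger:\n",
         paste(utils::capture.output(print(exclusions)), collapse = "\n"))
  }
  structure(list(per_day = per_day, days = day_tab,
                 exclusions = exclusions,
                 training_images = tr_imgs),
            class = "correct_error_result")
}
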