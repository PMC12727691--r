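# Representational dissimilarity (1 - Pearson r) between population
# response patterns, over image pairs drawn from different morph
# identities (same-identity pairs would confound visual similarity).

#' Trial-averaged, z-scored population response patterns
#'
#' For one region, averages each neuron's rate over an image's trials and
#' then z-scores each neuron across the image set, so dissimilarity
#' depends only on pattern shape. Boundary images are excluded by default.
#'
#' @param session A `neural_session`.
#' @param region `"TE"` or `"TEO"`.
#' @param include_boundary Keep the 50% images?
#' @return Matrix images x neurons, with `morph_identity`, `morph_level`
#'   and `category` attached as attribute `"images"`.
#' @export
mean_patterns <- function(session, region, include_boundary = FALSE) {
  pm <- build_population_matrix(session, region, include_boundary)
  key <- paste(pm$trials$morph_identity, pm$trials$morph_level)
  ix <- split(seq_len(nrow(pm$trials)), key)
  m <- t(vapply(ix, function(i) {
    colMeans(pm$counts[i, , drop = FALSE]) / session$window_s
  }, numeric(ncol(pm$counts))))
  parts <- strsplit(rownames(m), " ")
  images <- data.frame(
    morph_identity = as.integer(vapply(parts, `[`, "", 1)),
    morph_level = as.integer(vapply(parts, `[`, "", 2)))
  images$category <- assign_category(images$morph_level)
  z <- suppressWarnings(zscore_per_neuron(m))
  if (any(apply(m, 2, sd) == 0)) {
    warning("neuron(s) with identical responses to all images; ",
            "pattern entries set to 0")
  }
  attr(z, "images") <- images
  z
}

#' Population response pattern for one image
#'
#' @inheritParams mean_patterns
#' @param morph_identity,morph_level The image.
#' @return Numeric vector over the region's neurons.
#' @export
mean_pattern <- function(session, region, morph_identity, morph_level) {
  z <- mean_patterns(session, region, include_boundary = TRUE)
  img <- attr(z, "images")
  i <- which(img$morph_identity == morph_identity &
               img$morph_level == morph_level)
  if (length(i) != 1) stop("image has no trials in this session")
  z[i, ]
}

#' Correlation distance between two response patterns
#'
#' @param pattern_a,pattern_b Numeric vectors of equal length >= 2 with
#'   nonzero variance.
#' @return `1 - r` (Pearson), in \[0, 2\].
#' @export
pair_dissimilarity <- function(pattern_a, pattern_b) {
  if (length(pattern_a) != length(pattern_b) || length(pattern_a) < 2) {
    stop("patterns must have equal length >= 2")
  }
  if (sd(pattern_a) == 0 || sd(pattern_b) == 0) {
    stop("zero-variance pattern")
  }
  1 - cor(pattern_a, pattern_b)
}

#' Enumerate cross-identity image pairs of one class
#'
#' All unordered pairs of non-boundary images taken from different morph
#' identities, restricted to one pair class. For I identities and the
#' standard 5 + 5 non-boundary levels the counts are 25 I (I - 1)
#' between-category and 25 I (I - 1) / 2 per within-category class.
#'
#' @param stimulus_set data.frame as from [generate_stimulus_set()].
#' @param pair_class `"cat_vs_dog"`, `"cat_vs_cat"` or `"dog_vs_dog"`.
#' @return data.frame with columns `identity_a`, `level_a`, `identity_b`,
#'   `level_b`.
#' @export
enumerate_pairs <- function(stimulus_set,
                            pair_class = c("cat_vs_dog", "cat_vs_cat",
                                           "dog_vs_dog")) {
  pair_class <- match.arg(pair_class)
  s <- stimulus_set[stimulus_set$morph_level != 50, , drop = FALSE]
  if (length(unique(s$morph_identity)) < 2) {
    stop("need at least 2 morph identities")
  }
  cats <- which(s$category == "cat")
  dogs <- which(s$category == "dog")
  if (pair_class == "cat_vs_dog") {
    g <- expand.grid(a = cats, b = dogs)
  } else {
    ix <- if (pair_class == "cat_vs_cat") cats else dogs
    cmb <- combn(ix, 2)
    g <- data.frame(a = cmb[1, ], b = cmb[2, ])
  }
  keep <- s$morph_identity[g$a] != s$morph_identity[g$b]
  g <- g[keep, , drop = FALSE]
  data.frame(identity_a = s$morph_identity[g$a],
             level_a = s$morph_level[g$a],
             identity_b = s$morph_identity[g$b],
             level_b = s$morph_level[g$b])
}

#' Between- and within-category dissimilarity summary for one region
#'
#' Computes 1 - r for every cross-identity image pair and averages per
#' pair class; the SEM is taken over pairs, matching the pair-count n.
#'
#' @inheritParams mean_patterns
#' @return List of class `dissimilarity_table`: `summary` (per-class mean,
#'   SEM, n_pairs) and `pairs` (pair-level table with the class and
#'   dissimilarity of every pair).
#' @export
category_dissimilarity_summary <- function(session, region) {
  z <- mean_patterns(session, region)
  img <- attr(z, "images")
  cm <- cor(t(z))
  classes <- c("cat_vs_dog", "cat_vs_cat", "dog_vs_dog")
  pair_tabs <- lapply(classes, function(pc) {
    p <- enumerate_pairs(session$stimulus_set, pc)
    ia <- match(paste(p$identity_a, p$level_a),
                paste(img$morph_identity, img$morph_level))
    ib <- match(paste(p$identity_b, p$level_b),
                paste(img$morph_identity, img$morph_level))
    if (anyNA(ia) || anyNA(ib)) {
      stop("stimulus-set image(s) without trials in this session")
    }
    data.frame(pair_class = pc, p,
               dissimilarity = 1 - cm[cbind(ia, ib)])
  })
  pairs <- do.call(rbind, pair_tabs)
  summ <- do.call(rbind, lapply(split(pairs, pairs$pair_class), function(d) {
    data.frame(pair_class = d$pair_class[1], n_pairs = nrow(d),
               mean = mean(d$dissimilarity),
               sem = sd(d$dissimilarity) / sqrt(nrow(d)))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, pairs = pairs, region = region,
                 day = session$day),
            class = "dissimilarity_table")
}

#' @export
print.dissimilarity_table <- function(x, ...) {
  cat(sprintf("<dissimilarity_table> %s, day %d\n", x$region, x$day))
  print(x$summary)
  invisible(x)
}
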