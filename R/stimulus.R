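# Morph-matrix stimulus design: each morph identity is one cat-dog morph
# sequence; the morph level is the percent dog content of an image.

#' Morph levels of the standard cat--dog morph sequence
#'
#' The eleven percent-dog levels used to build each morph identity, densest
#' around the category boundary (50%).
#'
#' @return Integer vector of the 11 morph levels.
#' @export
morph_levels <- function() {
  c(0L, 25L, 35L, 40L, 45L, 50L, 55L, 60L, 65L, 75L, 100L)
}

#' Assign the category label of a morph level
#'
#' Images with less than 50% dog content are "cat", more than 50% are "dog",
#' and the 50% morph sits on the category boundary and belongs to neither.
#'
#' @param morph_level Integer vector of percent-dog morph levels; each must
#'   be one of [morph_levels()].
#' @return Character vector with elements `"cat"`, `"dog"` or `"boundary"`.
#' @examples
#' assign_category(c(45, 50, 55))
#' @export
assign_category <- function(morph_level) {
  bad <- setdiff(unique(morph_level), morph_levels())
  if (length(bad) > 0) {
    stop("unknown morph level(s): ", paste(bad, collapse = ", "),
         "; allowed levels are ", paste(morph_levels(), collapse = ", "))
  }
  ifelse(morph_level < 50, "cat", ifelse(morph_level > 50, "dog", "boundary"))
}

#' Generate the full morph-matrix stimulus set
#'
#' Crosses `n_identities` morph identities with the given morph levels,
#' yielding one image per (identity, level) cell with its derived category.
#'
#' @param n_identities Number of morph identities (>= 1).
#' @param levels Morph levels to use; a subset of [morph_levels()].
#' @return A data.frame with columns `morph_identity`, `morph_level`,
#'   `category`, one row per image.
#' @examples
#' nrow(generate_stimulus_set(10))  # 110 images
#' @export
generate_stimulus_set <- function(n_identities, levels = morph_levels()) {
  stopifnot(length(n_identities) == 1, n_identities >= 1)
  if (anyDuplicated(levels)) stop("duplicated morph levels")
  category <- assign_category(levels)
  out <- data.frame(
    morph_identity = rep(seq_len(n_identities), each = length(levels)),
    morph_level = rep(as.integer(levels), n_identities),
    category = rep(category, n_identities),
    stringsAsFactors = FALSE
  )
  out
}
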