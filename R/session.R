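# One recording day = one session: a neuron roster (TE/TEO, never tracked
# across days), a trial table, and a trials x neurons spike-count matrix.

CHOICES <- c("first_interval", "second_interval", "none")
OUTCOMES <- c("correct", "error", "neither")
REGIONS <- c("TE", "TEO")

#' Construct and validate a recording session
#'
#' Bundles one day's trials, spike counts and neuron roster into a
#' `neural_session` object, enforcing the data-model invariants: counts are
#' non-negative integers aligned with the roster, every trial's image is in
#' the stimulus set, and `outcome == "neither"` occurs only for boundary
#' (50% morph) images or skipped trials.
#'
#' @param day Integer day index (>= 1).
#' @param neurons data.frame with columns `neuron_id`, `region` ("TE"/"TEO"),
#'   `day`; `neuron_id` must be unique.
#' @param trials data.frame with columns `trial_id`, `day`, `morph_identity`,
#'   `morph_level`, `choice` ("first_interval"/"second_interval"/"none") and
#'   `outcome` ("correct"/"error"/"neither").
#' @param counts Integer matrix, one row per trial, one column per neuron
#'   (columns named by `neuron_id`), holding spike counts in the response
#'   window.
#' @param stimulus_set data.frame as from [generate_stimulus_set()].
#' @param window_s Response-window length in seconds (rate = count/window).
#' @return An object of class `neural_session`.
#' @seealso [simulate_session()], [write_session()], [load_session()]
#' @export
new_session <- function(day, neurons, trials, counts, stimulus_set, window_s) {
  counts <- as.matrix(counts)
  s <- structure(
    list(day = as.integer(day), neurons = neurons, trials = trials,
         counts = counts, stimulus_set = stimulus_set,
         window_s = as.numeric(window_s)),
    class = "neural_session"
  )
  validate_session(s)
  s
}

#' Validate a session object against the data-model invariants
#'
#' @param session A `neural_session`.
#' @return The session, invisibly; errors (naming offending rows) otherwise.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "neural_session"))
  n <- session$neurons
  t <- session$trials
  cn <- c("neuron_id", "region", "day")
  if (!all(cn %in% names(n))) {
    stop("neuron table is missing column(s): ",
         paste(setdiff(cn, names(n)), collapse = ", "))
  }
  tc <- c("trial_id", "day", "morph_identity", "morph_level", "choice",
          "outcome")
  if (!all(tc %in% names(t))) {
    stop("trial table is missing column(s): ",
         paste(setdiff(tc, names(t)), collapse = ", "))
  }
  if (anyDuplicated(n$neuron_id)) stop("duplicated neuron_id in roster")
  bad <- which(!n$region %in% REGIONS)
  if (length(bad) > 0) {
    stop("unknown region in neuron table row(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(session$window_s) != 1 || session$window_s <= 0) {
    stop("window_s must be a positive scalar")
  }
  cnt <- session$counts
  if (nrow(cnt) != nrow(t)) stop("count matrix rows != number of trials")
  if (ncol(cnt) != nrow(n)) stop("count matrix columns != roster length")
  if (!identical(colnames(cnt), as.character(n$neuron_id))) {
    stop("count matrix column names must equal neuron_id, in roster order")
  }
  bad <- which(apply(cnt, 1, function(x) {
    any(!is.finite(x)) || any(x < 0) || any(x != round(x))
  }))
  if (length(bad) > 0) {
    stop("counts must be non-negative integers; offending trial row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(!t$choice %in% CHOICES)
  if (length(bad) > 0) {
    stop("unknown choice in trial row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(!t$outcome %in% OUTCOMES)
  if (length(bad) > 0) {
    stop("unknown outcome in trial row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  key <- paste(t$morph_identity, t$morph_level)
  skey <- paste(session$stimulus_set$morph_identity,
                session$stimulus_set$morph_level)
  bad <- which(!key %in% skey)
  if (length(bad) > 0) {
    stop("trial row(s) reference image(s) not in the stimulus set: ",
         paste(head(bad, 5), collapse = ", "))
  }
  boundary <- t$morph_level == 50
  bad <- which(t$outcome == "neither" & !boundary & t$choice != "none")
  if (length(bad) > 0) {
    stop("outcome 'neither' only allowed for boundary images or skipped ",
         "trials; offending row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  invisible(session)
}

#' Write a session to plain-text files
#'
#' Writes three files sharing a stem: `<path>.trials.tsv` (trial metadata
#' followed by one count column per neuron), `<path>.neurons.tsv` (the
#' roster) and `<path>.json` (day, window and stimulus set). The output is
#' byte-stable for a given session, and [load_session()] inverts it exactly.
#'
#' @param session A valid `neural_session`.
#' @param path File stem (no extension).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  tab <- cbind(session$trials[, c("trial_id", "day", "morph_identity",
                                  "morph_level", "choice", "outcome")],
               as.data.frame(session$counts, check.names = FALSE))
  write.table(tab, paste0(path, ".trials.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(session$neurons[, c("neuron_id", "region", "day")],
              paste0(path, ".neurons.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(day = session$day, window_s = session$window_s,
               stimulus_set = session$stimulus_set)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path File stem used when writing.
#' @return A validated `neural_session`.
#' @export
load_session <- function(path) {
  f <- paste0(path, c(".trials.tsv", ".neurons.tsv", ".json"))
  missing <- f[!file.exists(f)]
  if (length(missing) > 0) {
    stop("missing session file(s): ", paste(missing, collapse = ", "))
  }
  tab <- read.delim(f[1], check.names = FALSE, stringsAsFactors = FALSE)
  neurons <- read.delim(f[2], stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(f[3], simplifyVector = TRUE)
  tc <- c("trial_id", "day", "morph_identity", "morph_level", "choice",
          "outcome")
  if (!all(tc %in% names(tab))) {
    stop("session table is missing column(s): ",
         paste(setdiff(tc, names(tab)), collapse = ", "))
  }
  count_cols <- setdiff(names(tab), tc)
  counts <- as.matrix(tab[, count_cols, drop = FALSE])
  if (nrow(tab) == 0) {
    counts <- matrix(integer(), 0, nrow(neurons),
                     dimnames = list(NULL, as.character(neurons$neuron_id)))
  }
  stim <- as.data.frame(meta$stimulus_set, stringsAsFactors = FALSE)
  neurons$neuron_id <- as.character(neurons$neuron_id)
  new_session(meta$day, neurons, tab[, tc], counts, stim, meta$window_s)
}

#' Extract the trials-by-neurons count matrix for one region
#'
#' Restricts columns to one region's neurons and (by default) drops trials
#' showing the boundary (50% morph) image, keeping the trial metadata
#' aligned row-for-row with the matrix.
#'
#' @param session A `neural_session`.
#' @param region `"TE"` or `"TEO"`.
#' @param include_boundary Keep 50%-image trials? Default `FALSE`.
#' @return List with `counts` (matrix), `trials` (aligned metadata) and
#'   `neurons` (the region roster).
#' @export
build_population_matrix <- function(session, region,
                                    include_boundary = FALSE) {
  validate_session(session)
  region <- match.arg(region, REGIONS)
  keep_n <- session$neurons$region == region
  if (!any(keep_n)) stop("no neurons recorded in region ", region)
  keep_t <- if (include_boundary) rep(TRUE, nrow(session$trials)) else
    session$trials$morph_level != 50
  list(counts = session$counts[keep_t, keep_n, drop = FALSE],
       trials = session$trials[keep_t, , drop = FALSE],
       neurons = session$neurons[keep_n, , drop = FALSE])
}

#' Behavioral correct rate of a session
#'
#' Fraction of correct among scored (correct/error) trials, excluding
#' boundary (50% morph) images, which belong to neither category.
#'
#' @param session A `neural_session`.
#' @return Fraction in \[0, 1\].
#' @export
behavioral_correct_rate <- function(session) {
  t <- session$trials
  keep <- t$morph_level != 50 & t$outcome %in% c("correct", "error")
  if (!any(keep)) stop("no scoreable (non-boundary correct/error) trials")
  mean(t$outcome[keep] == "correct")
}

#' @export
print.neural_session <- function(x, ...) {
  cat(sprintf(
    "<neural_session> day %d: %d trials, %d neurons (TE %d / TEO %d), %d images, window %.3f s\n",
    x$day, nrow(x$trials), nrow(x$neurons), sum(x$neurons$region == "TE"),
    sum(x$neurons$region == "TEO"), nrow(x$stimulus_set), x$window_s))
  invisible(x)
}
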