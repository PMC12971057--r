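# Bitscore cutoff calibration from labeled score distributions. A
# deterministic stand-in for the manual inspect-and-iterate loop used when
# profiles are built: when the positive and negative score distributions
# separate cleanly, the cutoff is placed midway between them.

#' Choose a bitscore cutoff from labeled scores
#'
#' If there are no negative scores the cutoff is half the smallest positive
#' score. Otherwise, if the distributions separate
#' (`min(positive) > max(negative)`) the cutoff is the midpoint
#' `(max(negative) + min(positive)) / 2`, which by construction keeps every
#' positive at or above the cutoff and every negative below it. If they do
#' not separate, no cutoff is returned (`separable = FALSE`): in practice
#' the profile's seed alignment must then be augmented with low-scoring
#' true hits and rebuilt, a human-in-the-loop step outside this package.
#'
#' @param positive_scores Numeric vector of bitscores of true hits
#'   (nonempty).
#' @param negative_scores Numeric vector of bitscores of false hits (may be
#'   empty).
#' @return A `cutoff_decision` list with `cutoff` (bits, or `NA` when
#'   inseparable), `separable` (logical), and `gap`
#'   (`min(positive) - max(negative)`, `NA` without negatives).
#' @examples
#' choose_cutoff(c(300, 400), c(50, 60))  # cutoff 180
#' choose_cutoff(c(200, 400), 250)        # inseparable
#' @export
choose_cutoff <- function(positive_scores, negative_scores = numeric(0)) {
  if (length(positive_scores) == 0L) {
    stop("at least one positive score is required", call. = FALSE)
  }
  stopifnot(all(is.finite(positive_scores)),
            all(is.finite(negative_scores)))
  if (length(negative_scores) == 0L) {
    return(structure(list(cutoff = min(positive_scores) / 2,
                          separable = TRUE, gap = NA_real_),
                     class = "cutoff_decision"))
  }
  gap <- min(positive_scores) - max(negative_scores)
  if (gap > 0) {
    structure(list(cutoff = (max(negative_scores) + min(positive_scores)) / 2,
                   separable = TRUE, gap = gap), class = "cutoff_decision")
  } else {
    structure(list(cutoff = NA_real_, separable = FALSE, gap = gap),
              class = "cutoff_decision")
  }
}

#' @export
print.cutoff_decision <- function(x, ...) {
  if (x$separable) {
    cat(sprintf("cutoff %.1f bits (separable%s)\n", x$cutoff,
                if (is.na(x$gap)) "" else sprintf(", gap %.1f", x$gap)))
  } else {
    cat(sprintf("inseparable (gap %.1f); augment the seed alignment\n",
                x$gap))
  }
  invisible(x)
}

#' Calibrate cutoffs for a table of labeled scores
#'
#' Applies [choose_cutoff()] per profile to a long table of
#' (profile, score, label) rows and returns a registry-compatible cutoff
#' table. Inseparable profiles get an `NA` cutoff and must be refined
#' before use.
#'
#' @param scores Data frame with columns `profile`, `score` (bits) and
#'   `label` (logical or `"positive"`/`"negative"`).
#' @return Data frame with columns `profile`, `cutoff`, `separable`,
#'   `gap`.
#' @export
calibrate_cutoffs <- function(scores) {
  stopifnot(all(c("profile", "score", "label") %in% names(scores)))
  lab <- scores$label
  if (!is.logical(lab)) lab <- tolower(as.character(lab)) == "positive"
  profs <- sort(unique(scores$profile))
  rows <- lapply(profs, function(p) {
    s <- scores[scores$profile == p, , drop = FALSE]
    d <- choose_cutoff(s$score[lab[scores$profile == p]],
                       s$score[!lab[scores$profile == p]])
    data.frame(profile = p, cutoff = d$cutoff, separable = d$separable,
               gap = d$gap, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
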