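# Benchmarking against curated truth: confusion counts,
# precision/recall/F1, census summaries, chelator-combination counts.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed summary statistics here
#' use conventional half-up rounding (0.8616 -> 0.86, 92.59 -> 93).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion counts of predictions against truth
#'
#' @param predictions Named logical vector (region key -> predicted
#'   positive).
#' @param truth Named logical vector over the identical key set.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(predictions, truth) {
  stopifnot(is.logical(predictions), is.logical(truth))
  if (!setequal(names(predictions), names(truth)) ||
      length(predictions) != length(truth)) {
    diff <- c(setdiff(names(predictions), names(truth)),
              setdiff(names(truth), names(predictions)))
    stop("prediction/truth key mismatch: ",
         paste(unique(diff), collapse = ", "), call. = FALSE)
  }
  truth <- truth[names(predictions)]
  structure(list(
    tp = sum(predictions & truth),
    fp = sum(predictions & !truth),
    fn = sum(!predictions & truth),
    tn = sum(!predictions & !truth)), class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f1 = 2*(precision*recall)/(precision+recall)`. A zero denominator makes
#' the affected metric 0 and sets `degenerate = TRUE` instead of producing
#' `NaN`, so batch benchmarking never crashes. Values are unrounded; use
#' [round_half_up()] (2 decimals, or whole percent) for reporting.
#'
#' @param counts A `confusion_counts` list, or anything with numeric
#'   `tp`/`fp`/`fn` fields.
#' @return A `metrics_report` list with `precision`, `recall`, `f1`,
#'   `degenerate`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, fp, fn) < 0)) stop("negative confusion counts", call. = FALSE)
  degenerate <- FALSE
  if (tp + fp == 0) { precision <- 0; degenerate <- TRUE }
  else precision <- tp / (tp + fp)
  if (tp + fn == 0) { recall <- 0; degenerate <- TRUE }
  else recall <- tp / (tp + fn)
  structure(list(precision = precision, recall = recall,
                 f1 = f1_score(precision, recall), degenerate = degenerate),
            class = "metrics_report")
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Values in \[0, 1\].
#' @return `2*(precision*recall)/(precision+recall)`, or 0 when both are 0.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.2f  recall %.2f  F1 %.2f%s\n",
              round_half_up(x$precision, 2), round_half_up(x$recall, 2),
              round_half_up(x$f1, 2),
              if (x$degenerate) "  (degenerate)" else ""))
  invisible(x)
}

#' Percentage at census rounding
#'
#' `100 * positive / total`, rounded half-up to the nearest whole percent,
#' except that one decimal is kept when the value is below 10 (so 8.63%
#' prints as 8.6, while 15.96% prints as 16).
#'
#' @param positive,total Counts.
#' @return A number, or `NA` when `total` is 0.
#' @export
census_percent <- function(positive, total) {
  if (total == 0) return(NA_real_)
  pct <- 100 * positive / total
  if (pct < 10) round_half_up(pct, 1L) else round_half_up(pct, 0L)
}

#' Census of classification results
#'
#' Tallies, per completeness stratum (complete, partial, total) and per
#' method (chelator rule, transporter rule, ensemble), the number of
#' regions, the number classified metallophore-positive, and the percentage
#' at [census_percent()] rounding. Stratum counts always sum to totals.
#'
#' @param results A data frame with logical columns `chelator_rule`,
#'   `transporter_rule`, `ensemble`, `complete` (e.g.
#'   `as.data.frame(detect(...))`), or a `metallophore_detection`.
#' @return A `census_summary`: data frame with one row per
#'   (method, stratum).
#' @export
census <- function(results) {
  if (inherits(results, "metallophore_detection")) {
    results <- as.data.frame(results)
  }
  stopifnot(is.data.frame(results))
  methods <- c("chelator_rule", "transporter_rule", "ensemble")
  strata <- list(complete = function(df) df[df$complete, , drop = FALSE],
                 partial = function(df) df[!df$complete, , drop = FALSE],
                 total = identity)
  rows <- list()
  for (m in methods) {
    for (s in names(strata)) {
      sub <- strata[[s]](results)
      n <- nrow(sub)
      pos <- if (n == 0L) 0L else sum(sub[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, stratum = s, n = n, positive = pos,
        percent = census_percent(pos, n), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("census_summary", "data.frame")
  out
}

#' Chelator-combination counts
#'
#' Each region contributes exactly one key: the sorted, semicolon-joined
#' tuple of its chelator groups. Regions with an empty profile are skipped,
#' so the counts sum to the number of nonempty profiles. The
#' `NRPS-domain-marker` pseudo-group (detection via VibH-like/tandem-Cy
#' domains rather than chelator biosynthesis) is kept as its own key only
#' when it is a region's sole evidence; alongside true chelator groups it
#' is dropped from the combination key.
#'
#' @param profiles A list of character vectors of chelator groups (e.g.
#'   `lapply(det$results, \[\[, "groups")`), or a
#'   `metallophore_detection`.
#' @return Named integer vector, sorted by key.
#' @export
combination_counts <- function(profiles) {
  if (inherits(profiles, "metallophore_detection")) {
    profiles <- lapply(profiles$results, `[[`, "groups")
  }
  keys <- vapply(profiles, function(g) {
    g <- sort(unique(g))
    if (length(g) > 1L) g <- setdiff(g, "NRPS-domain-marker")
    paste(g, collapse = ";")
  }, "")
  keys <- keys[nzchar(keys)]
  if (length(keys) == 0L) return(structure(integer(0), names = character(0)))
  tab <- table(keys)
  structure(as.integer(tab), names = names(tab))
}

#' Score a detection result against truth labels
#'
#' Matches each detected region to a truth label on the same contig (by
#' span overlap when the truth table carries `start`/`end`, otherwise by
#' contig identity), then computes confusion counts and metrics for one
#' method. Truth rows with no overlapping detected region count as false
#' negatives when positive and true negatives otherwise.
#'
#' @param detection A `metallophore_detection` or its data frame.
#' @param truth A truth data frame (see [read_truth_labels()]).
#' @param method One of `"chelator"`, `"transporter"`, `"ensemble"`.
#' @return A list with `counts` (`confusion_counts`) and `metrics`
#'   (`metrics_report`).
#' @export
evaluate_detection <- function(detection,
                               truth,
                               method = c("chelator", "transporter",
                                          "ensemble")) {
  method <- match.arg(method)
  col <- switch(method, chelator = "chelator_rule",
                transporter = "transporter_rule", ensemble = "ensemble")
  df <- if (inherits(detection, "metallophore_detection")) {
    as.data.frame(detection)
  } else detection
  have_span <- all(c("start", "end") %in% names(truth)) &&
    !anyNA(truth$start)
  pred <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    on_contig <- df[df$contig_id == truth$contig_id[i], , drop = FALSE]
    if (have_span && nrow(on_contig) > 0L) {
      on_contig <- on_contig[on_contig$start < truth$end[i] &
                             on_contig$end > truth$start[i], , drop = FALSE]
    }
    pred[i] <- nrow(on_contig) > 0L && any(on_contig[[col]])
  }
  keys <- if (have_span) {
    paste(truth$contig_id, truth$start, truth$end, sep = ":")
  } else truth$contig_id
  names(pred) <- keys
  tr <- stats::setNames(truth$is_metallophore, keys)
  counts <- confusion(pred, tr)
  list(counts = counts, metrics = compute_metrics(counts))
}
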