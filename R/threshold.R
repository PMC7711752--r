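# Equal-error-rate threshold between two adjacent rank strata.

#' Wrong-side shares of two strata at a candidate threshold
#'
#' For `orientation = "distance"` the lower stratum (e.g. within-species
#' pairs) is expected below the threshold and the higher stratum above it;
#' for `orientation = "similarity"` the expectation flips. A value exactly
#' at the threshold counts as correctly classified for the lower stratum
#' (so, wrongly for the higher one): floating-point ties are resolved the
#' same way on both sides of the comparison.
#'
#' @param lower Numeric values of the lower (more similar) stratum.
#' @param higher Numeric values of the higher (less similar) stratum.
#' @param threshold Candidate cut value.
#' @param orientation `"distance"` (smaller = more similar) or
#'   `"similarity"` (larger = more similar).
#' @return List with `share_lower_wrong`, `share_higher_wrong` and
#'   `pooled_misclassified` (wrong pairs over all pairs).
#' @export
wrong_side_shares <- function(lower, higher, threshold,
                              orientation = c("distance", "similarity")) {
  orientation <- match.arg(orientation)
  if (orientation == "distance") {
    wl <- sum(lower > threshold)
    wh <- sum(higher <= threshold)
  } else {
    wl <- sum(lower < threshold)
    wh <- sum(higher >= threshold)
  }
  list(share_lower_wrong = wl / length(lower),
       share_higher_wrong = wh / length(higher),
       pooled_misclassified = (wl + wh) / (length(lower) + length(higher)))
}

#' Pooled misclassification rate at a threshold
#'
#' Fraction of all pairs (both strata pooled) on the wrong side of the
#' threshold; classification accuracy is one minus this value.
#'
#' @inheritParams wrong_side_shares
#' @return Pooled misclassification rate in \[0, 1\].
#' @export
misclassification_rate <- function(lower, higher, threshold,
                                   orientation = c("distance", "similarity")) {
  wrong_side_shares(lower, higher, threshold, orientation)$pooled_misclassified
}

#' Equal-error threshold between two rank strata
#'
#' Binary search for the cut value at which the two strata leave (nearly)
#' equal shares of their pairs on the wrong side — the equal-error point.
#' The search bisects the closed interval between the two stratum medians:
#' at each midpoint the wrong-side shares are evaluated and the half
#' containing the stratum with the larger wrong-side share is kept. It stops
#' when the shares differ by less than `tolerance` or after `max_iter`
#' halvings, whichever comes first.
#'
#' When the two samples are indistinguishable the shares equalise near 0.5;
#' when they are perfectly separated the search settles anywhere in the gap
#' with both shares 0. The returned threshold always lies between the two
#' medians.
#'
#' @param lower,higher Non-empty numeric vectors of the two strata
#'   (lower = the more-similar stratum, e.g. within-species pairs).
#' @param orientation `"distance"` or `"similarity"`; declares which side of
#'   the threshold is correct for each stratum.
#' @param tolerance Stop when the wrong-side shares differ by less than this
#'   (default 1e-4).
#' @param max_iter Iteration cap of the bisection (default 100).
#' @return Object of class `eer_threshold`: `threshold`, `orientation`,
#'   `share_lower_wrong`, `share_higher_wrong`, `pooled_misclassified`,
#'   `iterations`, `converged`, plus sample sizes and the tolerance used.
#' @examples
#' lo <- rnorm(500, 0.02, 0.01); hi <- rnorm(500, 0.06, 0.01)
#' find_threshold(lo, hi, "distance")
#' @export
find_threshold <- function(lower, higher,
                           orientation = c("distance", "similarity"),
                           tolerance = 1e-4, max_iter = 100L) {
  orientation <- match.arg(orientation)
  if (length(lower) == 0L || length(higher) == 0L)
    stop("both strata must be non-empty")
  if (!all(is.finite(lower)) || !all(is.finite(higher)))
    stop("stratum values must be finite")
  m_lo <- median(lower)
  m_hi <- median(higher)
  a <- min(m_lo, m_hi)
  b <- max(m_lo, m_hi)
  iterations <- 0L
  converged <- FALSE
  t <- (a + b) / 2
  repeat {
    iterations <- iterations + 1L
    t <- (a + b) / 2
    sh <- wrong_side_shares(lower, higher, t, orientation)
    d <- sh$share_lower_wrong - sh$share_higher_wrong
    if (abs(d) < tolerance) { converged <- TRUE; break }
    if (iterations >= max_iter || a == b) break
    # move toward the stratum with the larger wrong-side share
    move_up <- if (orientation == "distance") d > 0 else d < 0
    if (move_up) a <- t else b <- t
  }
  structure(
    list(threshold = t, orientation = orientation,
         share_lower_wrong = sh$share_lower_wrong,
         share_higher_wrong = sh$share_higher_wrong,
         pooled_misclassified = sh$pooled_misclassified,
         iterations = iterations, converged = converged,
         n_lower = length(lower), n_higher = length(higher),
         tolerance = tolerance),
    class = "eer_threshold")
}

#' @export
print.eer_threshold <- function(x, digits = 6, ...) {
  cat(sprintf("Equal-error threshold (%s orientation): %.*g\n",
              x$orientation, digits, x$threshold))
  cat(sprintf("  wrong-side shares: lower %.4f (n=%d), higher %.4f (n=%d)\n",
              x$share_lower_wrong, x$n_lower,
              x$share_higher_wrong, x$n_higher))
  cat(sprintf("  pooled misclassified: %.4f (accuracy %.2f%%)\n",
              x$pooled_misclassified, 100 * (1 - x$pooled_misclassified)))
  cat(sprintf("  %d iteration(s), %sconverged (share tolerance %g)\n",
              x$iterations, if (x$converged) "" else "NOT ", x$tolerance))
  invisible(x)
}

#' Per-rank distance summaries
#'
#' Pair counts, medians and means of the distance (or similarity) values in
#' each taxonomic rank stratum, in rank order from species to phylum. Levels
#' without any pair are omitted.
#'
#' @param records Data frame of pairwise values with at least columns
#'   `level` and `value` (as produced by [compute_pairwise()]).
#' @return Data frame with columns `level`, `n_pairs`, `median`, `mean`.
#' @export
rank_summaries <- function(records) {
  stopifnot(all(c("level", "value") %in% names(records)))
  records <- records[!is.na(records$value), , drop = FALSE]
  if (nrow(records) == 0L)
    return(data.frame(level = character(), n_pairs = integer(),
                      median = numeric(), mean = numeric(),
                      stringsAsFactors = FALSE))
  sp <- split(records$value, records$level)
  lv <- intersect(RANK_LEVELS, names(sp))
  data.frame(level = lv,
             n_pairs = vapply(sp[lv], length, integer(1)),
             median = vapply(sp[lv], median, numeric(1)),
             mean = vapply(sp[lv], mean, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
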