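# Microhomology (muH) enumeration and scoring around a double-strand break.
#
# An MMEJ deletion pattern is a pair of exact repeats ("arms") of length
# lambda flanking the break -- the left copy ending at or before the cut, the
# right copy starting at or after it -- separated by `dist` intervening bases.
# Annealing the arms deletes one arm plus the spacer: del_len = lambda + dist.
# Patterns are weighted by the Bae-style pattern score
#   pi = 100 * round(exp(-del_len / 20), 3) * (lambda + gc_count),
# i.e. A/T arm bases weigh 1, G/C weigh 2, with exponential decay in the
# deletion length (decay constant 20 nt). The 3-decimal rounding of the length
# factor is applied before multiplication, matching the original published
# scoring code. Competition between the two strongest patterns at a site is
# summarised by the MENTHU score pi_max / pi_max-1.

#' Enumerate microhomology deletion patterns around a cut site
#'
#' Finds every exact-repeat arm pair of length `>= min_arm` whose collapse
#' deletes an interval spanning the break at `cut_index` (left arm entirely 5'
#' of the break, right arm entirely 3'; arms may abut the break). Patterns
#' producing an identical deletion product are deduplicated, keeping the
#' representative with maximal arm length (ties: smaller `dist`, then smaller
#' `left_start`).
#'
#' @param context Uppercase ACGT string; the sequence window around the break.
#' @param cut_index 0-based break position: the number of bases 5' of the
#'   break. Must satisfy `0 < cut_index < nchar(context)`.
#' @param min_arm Minimum arm length in nt (default 3, the conventional
#'   minimum for calling MMEJ).
#' @return A `data.frame` with one row per
#'   deduplicated pattern: `arm_seq`, `left_start`, `right_start` (0-based
#'   starts of the two arm copies), `lam` (arm length), `dist` (bases between
#'   the arms), `del_len` (`lam + dist`), `gc_count`, `score` (pattern score
#'   pi) and `product` (the deletion product). Rows are ordered by
#'   `left_start`, then `right_start`.
#' @seealso [menthu()] for the full scoring pipeline, [pattern_score()],
#'   [menthu_rank()].
#' @examples
#' enumerate_mh_patterns("AAGCATTTGCATCC", cut_index = 7)
#' @export
enumerate_mh_patterns <- function(context, cut_index, min_arm = 3L) {
  .assert_dna(context)
  n <- nchar(context)
  cut_index <- as.integer(cut_index)
  if (is.na(cut_index) || cut_index <= 0L || cut_index >= n) {
    stop("`cut_index` must lie strictly inside the context (0 < cut < ",
         n, "), got ", cut_index, call. = FALSE)
  }
  min_arm <- as.integer(min_arm)
  if (is.na(min_arm) || min_arm < 2L) stop("`min_arm` must be >= 2", call. = FALSE)

  s <- .chars(context)
  rec <- list()
  # Left arm starts i (0-based) must allow the arm to end at or before the
  # cut; right arm starts j must be at or after the cut.
  i_max <- cut_index - min_arm
  for (i in seq_len(i_max + 1L) - 1L) {
    if (i_max < 0L) break
    for (j in seq.int(cut_index, n - min_arm)) {
      if (j <= i) next
      # Maximal usable arm length for this pair: bounded by the raw common
      # extension, a non-negative spacer, the cut (left arm 5' of break), and
      # the sequence end.
      lim <- min(j - i, n - j, cut_index - i)
      k <- 0L
      while (k < lim && s[i + k + 1L] == s[j + k + 1L]) k <- k + 1L
      if (k < min_arm) next
      lam <- k
      rec[[length(rec) + 1L]] <- c(i = i, j = j, lam = lam)
    }
  }
  if (length(rec) == 0L) return(.empty_mh_patterns())

  m <- do.call(rbind, rec)
  i <- m[, "i"]; j <- m[, "j"]; lam <- m[, "lam"]
  del_len <- j - i
  dist <- del_len - lam
  product <- vapply(seq_along(i), function(r) {
    paste0(substr(context, 1L, i[r]), substr(context, j[r] + 1L, n))
  }, character(1))
  arm_seq <- substr(rep(context, length(i)), i + 1L, i + lam)

  df <- data.frame(
    arm_seq = arm_seq, left_start = i, right_start = j,
    lam = lam, dist = dist, del_len = del_len,
    gc_count = vapply(arm_seq,
                      function(a) sum(.chars(a) %in% c("G", "C")),
                      integer(1), USE.NAMES = FALSE),
    product = product, stringsAsFactors = FALSE
  )
  # Dedup identical products: keep max lambda, then smaller dist / left_start.
  ord <- order(df$product, -df$lam, df$dist, df$left_start)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df$product), , drop = FALSE]
  df$score <- pattern_score(df)
  df <- df[order(df$left_start, df$right_start), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("arm_seq", "left_start", "right_start", "lam", "dist",
         "del_len", "gc_count", "score", "product")]
}

.empty_mh_patterns <- function() {
  df <- data.frame(
    arm_seq = character(0), left_start = integer(0), right_start = integer(0),
    lam = integer(0), dist = integer(0), del_len = integer(0),
    gc_count = integer(0), score = numeric(0), product = character(0),
    stringsAsFactors = FALSE
  )
  df
}

#' Bae-style pattern score for microhomology deletion patterns
#'
#' Computes `pi = 100 * round(exp(-del_len/20), 3) * (lam + gc_count)`:
#' G/C arm bases weigh 2, A/T bases 1, with exponential decay in the deleted
#' length. The length factor is rounded to 3 decimals before multiplication,
#' for fidelity with the original published scoring.
#'
#' @param p A `data.frame` (e.g. from [enumerate_mh_patterns()]) or list with
#'   fields `lam`, `del_len` and `gc_count` (vectors allowed).
#' @return Numeric vector of pattern scores, one per row.
#' @examples
#' pattern_score(data.frame(lam = 4, del_len = 6, gc_count = 2))  # 444.6
#' @export
pattern_score <- function(p) {
  lam <- as.numeric(p$lam)
  del_len <- as.numeric(p$del_len)
  gc <- as.numeric(p$gc_count)
  if (length(lam) == 0L) return(numeric(0))
  if (anyNA(lam) || anyNA(del_len) || anyNA(gc)) {
    stop("pattern has missing lam/del_len/gc_count", call. = FALSE)
  }
  if (any(lam < 1)) stop("arm length must be positive", call. = FALSE)
  if (any(del_len < lam)) {
    stop("inconsistent pattern: del_len < lam (the deletion removes one arm ",
         "copy plus the spacer, so del_len >= lam)", call. = FALSE)
  }
  100 * round(exp(-del_len / 20), 3) * (lam + gc)
}

#' Rank microhomology patterns and compute the MENTHU score
#'
#' Sorts patterns by descending pattern score (ties: smaller `dist`, then
#' smaller `left_start`) and computes the MENTHU score, the ratio of the top
#' two pattern scores `pi_max / pi_max-1`. A site with a single candidate
#' pattern has no competitor and is assigned `Inf`; a site with no pattern has
#' an undefined (`NA`) score and is never a PreMA.
#'
#' @param patterns A pattern data frame from [enumerate_mh_patterns()].
#' @param cut_index 0-based break position the patterns were enumerated at.
#' @param score_threshold,dist_threshold PreMA thresholds forwarded to
#'   [classify_prema()] (defaults 1.50 and 5, both inclusive).
#' @return An object of class `menthu_result`: a list with `cut_index`,
#'   `patterns` (ranked), `menthu_score`, `top_dist`, `top_del_len`,
#'   `top_frameshift` (top deletion length not a multiple of 3) and
#'   `is_prema`.
#' @examples
#' p <- enumerate_mh_patterns("AAGCATTTGCATCC", 7)
#' menthu_rank(p, 7)
#' @export
menthu_rank <- function(patterns, cut_index, score_threshold = 1.5,
                        dist_threshold = 5L) {
  stopifnot(is.data.frame(patterns))
  if (is.null(patterns$score) && nrow(patterns) > 0L) {
    patterns$score <- pattern_score(patterns)
  }
  if (nrow(patterns) > 0L) {
    ord <- order(-patterns$score, patterns$dist, patterns$left_start)
    patterns <- patterns[ord, , drop = FALSE]
    rownames(patterns) <- NULL
  }
  n <- nrow(patterns)
  menthu_score <- if (n == 0L) NA_real_
    else if (n == 1L) Inf
    else patterns$score[1L] / patterns$score[2L]
  res <- structure(list(
    cut_index = as.integer(cut_index),
    patterns = patterns,
    menthu_score = menthu_score,
    top_dist = if (n > 0L) patterns$dist[1L] else NA_integer_,
    top_del_len = if (n > 0L) patterns$del_len[1L] else NA_integer_,
    top_frameshift = if (n > 0L) (patterns$del_len[1L] %% 3L) != 0L else NA,
    score_threshold = score_threshold,
    dist_threshold = as.integer(dist_threshold),
    is_prema = FALSE
  ), class = "menthu_result")
  res$is_prema <- classify_prema(res, score_threshold, dist_threshold)
  res
}

#' PreMA classification from a ranked MENTHU result
#'
#' A site is called a predominant-MMEJ-allele (PreMA) reagent when the MENTHU
#' score is at least `score_threshold` AND the distance between the top
#' pattern's arms is at most `dist_threshold`; both comparisons are
#' inclusive. Distance presets 3/4/5/6 correspond to the MENTHU@3/@4/@5/@6
#' variants (5 is the original).
#'
#' @param result A `menthu_result` from [menthu_rank()] or [menthu()].
#' @param score_threshold Minimum MENTHU score (default 1.50).
#' @param dist_threshold Maximum arm distance in bp (default 5).
#' @return Logical scalar.
#' @export
classify_prema <- function(result, score_threshold = 1.5, dist_threshold = 5L) {
  stopifnot(inherits(result, "menthu_result"))
  if (!is.numeric(score_threshold) || score_threshold <= 0 ||
      !is.numeric(dist_threshold) || dist_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (is.na(result$menthu_score)) return(FALSE)
  isTRUE(result$menthu_score >= score_threshold &&
         result$top_dist <= dist_threshold)
}

#' Score a cut site: enumerate, rank and classify in one call
#'
#' @inheritParams enumerate_mh_patterns
#' @inheritParams classify_prema
#' @return A `menthu_result`; see [menthu_rank()].
#' @examples
#' menthu("AAGCATTTGCATCC", cut_index = 7)
#' @export
menthu <- function(context, cut_index, min_arm = 3L, score_threshold = 1.5,
                   dist_threshold = 5L) {
  menthu_rank(enumerate_mh_patterns(context, cut_index, min_arm), cut_index,
              score_threshold, dist_threshold)
}

#' Apply a deletion to a sequence
#'
#' Removes the half-open interval `[left, left + del_len)` (0-based) from
#' `context`.
#'
#' @param context DNA string.
#' @param left 0-based start of the deleted interval.
#' @param del_len Deletion length in nt.
#' @return The deletion product.
#' @examples
#' apply_deletion("AAGCATTTGCATCC", 2, 6)  # "AAGCATCC"
#' @export
apply_deletion <- function(context, left, del_len) {
  stopifnot(is.character(context), length(context) == 1L)
  n <- nchar(context)
  left <- as.integer(left); del_len <- as.integer(del_len)
  if (is.na(left) || is.na(del_len) || left < 0L || del_len < 0L ||
      left + del_len > n) {
    stop("deletion interval [", left, ", ", left + del_len,
         ") out of bounds for sequence of length ", n, call. = FALSE)
  }
  paste0(substr(context, 1L, left), substr(context, left + del_len + 1L, n))
}

#' @export
print.menthu_result <- function(x, ...) {
  n <- nrow(x$patterns)
  cat("MENTHU site summary (cut at ", x$cut_index, ", 0-based)\n", sep = "")
  cat("  candidate MMEJ patterns: ", n, "\n", sep = "")
  if (n > 0L) {
    top <- x$patterns[1L, ]
    cat(sprintf("  top pattern: arm %s  lam=%d  dist=%d  del_len=%d  pi=%.1f\n",
                top$arm_seq, top$lam, top$dist, top$del_len, top$score))
  }
  cat(sprintf("  MENTHU score: %s  (thresholds: score >= %.2f, dist <= %d)\n",
              format(x$menthu_score), x$score_threshold, x$dist_threshold))
  cat("  PreMA: ", x$is_prema,
      "   top frameshift: ", x$top_frameshift, "\n", sep = "")
  invisible(x)
}
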