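# MENdel: combining deletion-based PreMA calls with single-majority 1 bp
# insertion calls from an external insertion predictor.
#
# External predictors are consumed through an adapter contract: a function
# taking a 60-nt window (break after position 30) and returning an
# `outcome_distribution` of per-outcome probabilities. The published Lindel
# model plugs in through this contract when available; a deterministic mock
# and a null adapter ship for testing and for MENTHU-only operation.

#' Construct an outcome distribution from an external predictor
#'
#' Outcomes may be given as indel descriptors (`outcome_kind`
#' `"deletion"`/`"insertion"`, `indel_len`, `position` 0-based,
#' `inserted_seq`) or as predicted repaired sequences (column `sequence`),
#' each with a `probability`. Probabilities must sum to 1 within `1e-6` and
#' are renormalised (adapter outputs may round); outcomes are sorted by
#' descending probability (stable for ties).
#'
#' @param outcomes Data frame of outcomes as above.
#' @param cut_index 0-based break position in the adapter's input window
#'   (default 30 for a 60-nt window).
#' @param source Adapter name, for provenance.
#' @return A list of class `outcome_distribution`.
#' @export
outcome_distribution <- function(outcomes, cut_index = 30L, source = "adapter") {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) > 0L,
            "probability" %in% names(outcomes))
  p <- as.numeric(outcomes$probability)
  if (anyNA(p) || any(p < 0)) stop("invalid outcome probabilities", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6) {
    stop("outcome probabilities sum to ", format(sum(p)),
         "; expected 1 within 1e-6", call. = FALSE)
  }
  outcomes$probability <- p / sum(p)
  outcomes <- outcomes[order(-outcomes$probability), , drop = FALSE]
  rownames(outcomes) <- NULL
  structure(list(outcomes = outcomes, cut_index = as.integer(cut_index),
                 source = source),
            class = "outcome_distribution")
}

# Resolve the top outcome of a distribution to (kind, length, left,
# inserted_seq). Sequence-form outcomes are reconciled against the WT window
# as a single simple indel; irreconcilable sequences are an adapter-format
# error.
.top_outcome_call <- function(dist, wt_context = NULL) {
  top <- dist$outcomes[1L, ]
  if (!is.null(top$outcome_kind) && !is.na(top$outcome_kind)) {
    list(kind = as.character(top$outcome_kind),
         length = as.integer(top$indel_len),
         left = if (is.null(top$position)) NA_integer_ else as.integer(top$position),
         prob = top$probability)
  } else if (!is.null(top$sequence) && !is.na(top$sequence)) {
    if (is.null(wt_context)) {
      stop("adapter returned sequence-form outcomes but no WT context is ",
           "available to reconcile them", call. = FALSE)
    }
    call <- align_simple_indel(wt_context, top$sequence)
    if (is.null(call)) {
      stop("adapter-format error: top outcome sequence is not reconcilable ",
           "with the WT context as a single simple indel", call. = FALSE)
    }
    list(kind = call$kind, length = call$length, left = call$left,
         prob = top$probability)
  } else {
    stop("adapter-format error: outcome rows need either `outcome_kind` ",
         "descriptors or a `sequence` column", call. = FALSE)
  }
}

#' PreMA call from an external predictor's outcome distribution
#'
#' Applies the distribution-based PreMA rule: the site is a PreMA when the
#' most likely outcome has probability at or above `p_threshold` (default
#' 0.50, inclusive) AND is a deletion displaying the MMEJ pattern (junction
#' microhomology of at least 3 nt in the WT window at the predicted
#' interval).
#'
#' @param dist An `outcome_distribution`.
#' @param wt_context WT window the adapter was run on.
#' @param cut_index 0-based break position in `wt_context` (kept for the
#'   adapter contract; the junction test itself is position-free).
#' @param p_threshold Minimum top-outcome probability (default 0.50).
#' @return Logical scalar.
#' @export
prema_from_distribution <- function(dist, wt_context, cut_index = NULL,
                                    p_threshold = 0.5) {
  stopifnot(inherits(dist, "outcome_distribution"))
  .assert_dna(wt_context)
  top <- .top_outcome_call(dist, wt_context)
  if (top$prob < p_threshold) return(FALSE)
  if (!identical(top$kind, "deletion")) return(FALSE)
  if (is.na(top$left) || is.na(top$length)) {
    stop("adapter-format error: deletion outcome lacks position/length",
         call. = FALSE)
  }
  junction_microhomology(wt_context, top$left, top$length) >= 3L
}

#' Single-majority 1 bp insertion call from an outcome distribution
#'
#' @inheritParams prema_from_distribution
#' @return `TRUE` iff the most likely outcome is a 1 bp insertion with
#'   probability at or above `p_threshold` (inclusive).
#' @export
sm_insertion_from_distribution <- function(dist, p_threshold = 0.5) {
  stopifnot(inherits(dist, "outcome_distribution"))
  top <- dist$outcomes[1L, ]
  kind <- if (!is.null(top$outcome_kind)) as.character(top$outcome_kind) else NA_character_
  len <- if (!is.null(top$indel_len)) as.integer(top$indel_len) else NA_integer_
  if (is.na(kind)) {
    stop("adapter-format error: cannot determine the top outcome kind; ",
         "provide descriptor columns (`outcome_kind`, `indel_len`)",
         call. = FALSE)
  }
  isTRUE(kind == "insertion" && len == 1L && top$probability >= p_threshold)
}

#' MENdel: combined deletion + insertion frameshift call for one site
#'
#' Runs the microhomology engine on a 60-nt window (break after position 30)
#' for the PreMA deletion call, queries the insertion adapter for a
#' single-majority 1 bp insertion call, and combines them: the site is
#' predicted to yield a single-majority frameshift when the PreMA deletion is
#' out of frame (top deletion length not a multiple of 3) or a 1 bp
#' insertion majority is predicted (every 1 bp insertion is out of frame).
#'
#' @param context60 60-nt ACGT window with the break after position 30.
#' @param insertion_adapter Function `(context60) -> outcome_distribution`;
#'   see [mock_insertion_adapter()] and [null_insertion_adapter()].
#' @param score_threshold,dist_threshold PreMA thresholds (defaults 1.50, 5).
#' @param p_threshold Insertion probability threshold (default 0.50).
#' @return A list of class `mendel_call` with `prema_deletion`,
#'   `deletion_frameshift`, `sm_insertion`, `frameshift_call` and the
#'   underlying `menthu_result`.
#' @examples
#' ctx <- paste(rep("ACGT", 15), collapse = "")
#' mendel_predict(ctx, null_insertion_adapter())
#' @export
mendel_predict <- function(context60, insertion_adapter,
                           score_threshold = 1.5, dist_threshold = 5L,
                           p_threshold = 0.5) {
  .assert_dna(context60)
  if (nchar(context60) != 60L) {
    stop("MENdel requires a 60-nt window (break after position 30); got ",
         nchar(context60), " nt", call. = FALSE)
  }
  if (!is.function(insertion_adapter)) {
    stop("`insertion_adapter` must be a function taking the 60-nt window",
         call. = FALSE)
  }
  res <- menthu(context60, 30L, score_threshold = score_threshold,
                dist_threshold = dist_threshold)
  dist <- tryCatch(insertion_adapter(context60), error = function(e) {
    stop("insertion adapter failed on window ", substr(context60, 1, 12),
         "...: ", conditionMessage(e), call. = FALSE)
  })
  if (!inherits(dist, "outcome_distribution")) {
    stop("insertion adapter must return an `outcome_distribution`",
         call. = FALSE)
  }
  sm_ins <- sm_insertion_from_distribution(dist, p_threshold)
  prema <- res$is_prema
  del_fs <- isTRUE(res$top_frameshift)
  structure(list(
    prema_deletion = prema,
    deletion_frameshift = del_fs,
    sm_insertion = sm_ins,
    frameshift_call = (prema && del_fs) || sm_ins,
    menthu = res
  ), class = "mendel_call")
}

#' Deterministic mock insertion adapter
#'
#' Returns an adapter whose distribution puts `p_insertion` on a 1 bp
#' insertion at the break and the remaining mass on a generic deletion; used
#' in tests and examples in place of a trained insertion predictor.
#'
#' @param p_insertion Probability assigned to the 1 bp insertion.
#' @param base Inserted base.
#' @return A function usable as `insertion_adapter` in [mendel_predict()].
#' @export
mock_insertion_adapter <- function(p_insertion = 0.55, base = "A") {
  stopifnot(is.numeric(p_insertion), p_insertion >= 0, p_insertion <= 1)
  force(base)
  function(context60) {
    outcome_distribution(data.frame(
      outcome_kind = c("insertion", "deletion"),
      indel_len = c(1L, 3L),
      position = c(30L, 28L),
      inserted_seq = c(base, NA_character_),
      probability = c(p_insertion, 1 - p_insertion),
      stringsAsFactors = FALSE
    ), cut_index = 30L, source = "mock")
  }
}

#' Null insertion adapter (insertion probability always 0)
#'
#' With this adapter MENdel calls reduce exactly to MENTHU frameshift-PreMA
#' calls.
#'
#' @return A function usable as `insertion_adapter` in [mendel_predict()].
#' @export
null_insertion_adapter <- function() mock_insertion_adapter(0)

#' Empirical outcome distribution of an observed read pool
#'
#' Treats an event's consolidated reads as an outcome distribution
#' (probability = read frequency), resolving each read to an indel
#' descriptor where it is explained by a single simple indel (others keep
#' kind `"other"`). Useful as a perfect-information adapter on simulated
#' data, and to replay observed pools through the distribution-based rules.
#'
#' @param event A `repair_event`.
#' @return An `outcome_distribution`.
#' @export
empirical_outcome_distribution <- function(event) {
  stopifnot(inherits(event, "repair_event"))
  rows <- lapply(seq_len(nrow(event$reads)), function(i) {
    sq <- event$reads$seq[i]
    call <- if (sq == event$wt) NULL else align_simple_indel(event$wt, sq)
    data.frame(
      outcome_kind = if (is.null(call)) "other" else call$kind,
      indel_len = if (is.null(call)) NA_integer_ else call$length,
      position = if (is.null(call)) NA_integer_ else call$left,
      inserted_seq = if (is.null(call)) NA_character_ else
        if (is.na(call$inserted_seq)) NA_character_ else call$inserted_seq,
      probability = event$reads$count[i] / event$total_reads,
      sequence = sq, stringsAsFactors = FALSE
    )
  })
  outcome_distribution(do.call(rbind, rows), cut_index = event$cut_index,
                       source = "empirical")
}

#' Read an adapter's outcome distribution from TSV or JSON
#'
#' @param path File path; `.json` is parsed with jsonlite, anything else as
#'   TSV. Columns as in [outcome_distribution()].
#' @param cut_index,source Passed to [outcome_distribution()].
#' @return An `outcome_distribution`.
#' @export
read_adapter_output <- function(path, cut_index = 30L, source = basename(path)) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  outcome_distribution(df, cut_index = cut_index, source = source)
}

#' @export
print.mendel_call <- function(x, ...) {
  cat("MENdel call\n")
  cat("  PreMA deletion: ", x$prema_deletion,
      " (frameshift: ", x$deletion_frameshift, ")\n", sep = "")
  cat("  single-majority 1 bp insertion: ", x$sm_insertion, "\n", sep = "")
  cat("  frameshift call: ", x$frameshift_call, "\n", sep = "")
  invisible(x)
}
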