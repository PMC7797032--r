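# Ground-truth labelling of repair-read pools.
#
# The most frequent read of each event is aligned globally to its WT sequence
# with a substitution scheme that heavily penalises mismatches (match = 1,
# mismatch = -50; gap opening 10 / extension 4, the pairwiseAlignment
# defaults). Only alignments explained by a single, simple indel are
# included. Deletions are MMEJ when the junction carries >= 3 nt of exact
# microhomology; a single-majority call additionally requires the top read to
# comprise at least half of the pool.

.submat_5050 <- local({
  b <- c("A", "C", "G", "T")
  m <- matrix(-50, 4, 4, dimnames = list(b, b))
  diag(m) <- 1
  m
})

#' Call a single simple indel between a WT sequence and a repaired read
#'
#' Globally aligns `read` to `wt` (match = 1, mismatch = -50, gap opening 10,
#' gap extension 4) and returns an indel call only when the optimal alignment
#' consists of exactly one contiguous gap in exactly one sequence and zero
#' mismatches; anything else (no change, substitutions, multiple indels)
#' returns `NULL`, i.e. the read is excluded. Ambiguous indel placement is
#' canonicalised to the leftmost position; for deletions the junction
#' microhomology is computed (placement-invariant) and the call categorised.
#'
#' @param wt,read Non-empty uppercase ACGT strings.
#' @return `NULL`, or a list of class `indel_call` with `kind`
#'   (`"deletion"`/`"insertion"`), `length`, `left` (0-based deletion start or
#'   insertion point in WT coordinates), `inserted_seq`, `mh_len` (junction
#'   microhomology, deletions only) and `category` (one of `"MMEJ_del"`,
#'   `"nonMMEJ_del"`, `"ins_1bp"`, `"ins_multi"`).
#' @examples
#' align_simple_indel("AAGCATTTGCATCC", "AAGCATCC")
#' @export
align_simple_indel <- function(wt, read) {
  .assert_dna(wt); .assert_dna(read)
  if (wt == read) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    read, wt, substitutionMatrix = .submat_5050,
    gapOpening = 10, gapExtension = 4, type = "global"
  )
  n_ins <- length(Biostrings::insertion(pa)[[1L]])  # extra bases in the read
  n_del <- length(Biostrings::deletion(pa)[[1L]])   # bases missing from read
  # a terminal gap is not reported in the indel ranges, so "at most one
  # reported gap" is combined with the exact prefix/suffix criterion below,
  # which certifies the one-contiguous-gap, zero-mismatch structure for
  # interior and terminal indels alike
  if (Biostrings::nmismatch(pa) != 0L || n_ins + n_del > 1L) return(NULL)

  nw <- nchar(wt); nr <- nchar(read)
  if (nw == nr) return(NULL)  # a lone gap cannot preserve equal lengths
  a <- .chars(wt); b <- .chars(read)
  p <- .lcp(a, b); s <- .lcs(a, b)
  d <- abs(nw - nr)
  if (p + s < min(nw, nr)) return(NULL)  # not a single clean indel

  if (nw > nr) {                         # deletion from WT
    left <- max(0L, nr - s)              # leftmost placement
    stopifnot(left <= p, apply_deletion(wt, left, d) == read)
    mh <- junction_microhomology(wt, left, d)
    structure(list(
      kind = "deletion", length = d, left = left, inserted_seq = NA_character_,
      mh_len = mh,
      category = if (mh >= 3L) "MMEJ_del" else "nonMMEJ_del"
    ), class = "indel_call")
  } else {                               # insertion into WT
    left <- max(0L, nw - s)              # leftmost insertion point
    stopifnot(left <= p)
    ins <- substr(read, left + 1L, left + d)
    stopifnot(paste0(substr(wt, 1L, left), ins,
                     substr(wt, left + 1L, nw)) == read)
    structure(list(
      kind = "insertion", length = d, left = left, inserted_seq = ins,
      mh_len = NA_integer_,
      category = if (d == 1L) "ins_1bp" else "ins_multi"
    ), class = "indel_call")
  }
}

#' Junction microhomology of a deletion
#'
#' The MMEJ signature of a deletion is exact homology between the deleted
#' segment and the retained flank at the junction. Over all equivalent
#' placements of the same deletion product, `junction_microhomology` returns
#' the largest `k` such that the deleted segment shares a `k`-nt prefix with
#' the retained downstream flank or a `k`-nt suffix with the retained
#' upstream flank. The value is placement-invariant; a deletion is called
#' MMEJ when `k >= 3`.
#'
#' @param wt DNA string.
#' @param left 0-based start of the deleted interval.
#' @param del_len Deletion length in nt.
#' @return Integer `k >= 0`.
#' @examples
#' junction_microhomology("AAGCATTTGCATCC", 2, 6)  # 4
#' @export
junction_microhomology <- function(wt, left, del_len) {
  .assert_dna(wt)
  n <- nchar(wt)
  left <- as.integer(left); del_len <- as.integer(del_len)
  if (is.na(left) || is.na(del_len) || left < 0L || del_len < 1L ||
      left + del_len > n) {
    stop("deletion interval out of bounds", call. = FALSE)
  }
  a <- .chars(wt)
  # All placements of the same product form a contiguous slide range.
  i <- left
  while (i > 0L && a[i] == a[i + del_len]) i <- i - 1L
  j <- left
  while (j + del_len < n && a[j + 1L] == a[j + del_len + 1L]) j <- j + 1L
  k <- 0L
  for (pos in i:j) {
    deleted <- a[(pos + 1L):(pos + del_len)]
    down <- if (pos + del_len < n) a[(pos + del_len + 1L):n] else character(0)
    up <- if (pos > 0L) a[1:pos] else character(0)
    k <- max(k, .lcp(deleted, down), .lcs(deleted, up))
  }
  k
}

#' Load repair events from the canonical TSV schema
#'
#' Reads a tab-separated file with columns `event_id`, `wt`, `cut_index`,
#' `read_seq`, `count` (and an optional logical `genomic` curation flag
#' marking reads from genuine genomic targets). Rows are grouped by event,
#' duplicate `(event, sequence)` rows have their counts summed, and each
#' pool is ranked by descending count (ties broken lexicographically).
#' Malformed rows (non-ACGT reads, non-positive counts) are dropped with a
#' warning naming their line numbers.
#'
#' @param path Path to the events TSV.
#' @return A list of `repair_event` objects, each a list with `event_id`,
#'   `wt`, `cut_index`, `reads` (data frame `seq`, `count`), `total_reads`,
#'   `top_read`, `top_freq` and `genomic`.
#' @export
load_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = NA, check.names = TRUE)
  required <- c("event_id", "wt", "cut_index", "read_seq", "count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("events file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("events file contains no rows")
    return(list())
  }
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- !grepl("^[ACGT]+$", df$read_seq) | !grepl("^[ACGT]+$", df$wt) |
    is.na(df$count) | df$count < 1
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed row(s) at line(s): ",
            paste(df$.line[bad], collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) return(list())
  lapply(split(df, df$event_id)[unique(df$event_id)], function(g) {
    reads <- stats::aggregate(count ~ read_seq, data = g, FUN = sum)
    reads <- reads[order(-reads$count, reads$read_seq), , drop = FALSE]
    names(reads) <- c("seq", "count")
    rownames(reads) <- NULL
    repair_event(
      event_id = g$event_id[1L], wt = g$wt[1L],
      cut_index = as.integer(g$cut_index[1L]), reads = reads,
      genomic = if ("genomic" %in% names(g)) isTRUE(as.logical(g$genomic[1L])) else TRUE
    )
  })
}

#' Construct a repair event from a consolidated read pool
#'
#' @param event_id Identifier string.
#' @param wt WT sequence.
#' @param cut_index 0-based break position in `wt`.
#' @param reads Data frame with columns `seq` and `count`; consolidated and
#'   re-ranked here (descending count, lexicographic tie-break).
#' @param genomic Curation flag: does the event target a genuine genomic
#'   sequence (default `TRUE`)?
#' @return A `repair_event` object.
#' @export
repair_event <- function(event_id, wt, cut_index, reads, genomic = TRUE) {
  .assert_dna(wt)
  stopifnot(is.data.frame(reads), all(c("seq", "count") %in% names(reads)),
            nrow(reads) > 0L, all(reads$count >= 1))
  agg <- stats::aggregate(count ~ seq, data = reads, FUN = sum)
  agg <- agg[order(-agg$count, agg$seq), , drop = FALSE]
  rownames(agg) <- NULL
  total <- sum(agg$count)
  structure(list(
    event_id = as.character(event_id), wt = wt,
    cut_index = as.integer(cut_index),
    reads = agg, total_reads = total,
    top_read = agg$seq[1L], top_freq = agg$count[1L] / total,
    genomic = isTRUE(genomic)
  ), class = "repair_event")
}

#' Label a repair event (PreMA / single-majority insertion / frameshift)
#'
#' Applies the inclusion and classification rules to a consolidated pool:
#' the event is included when its most frequent read is explained by a
#' single simple indel; the indel is categorised (MMEJ vs non-MMEJ deletion
#' via the junction-microhomology test, 1 bp vs longer insertion); and
#' single-majority calls require the top read to hold at least 50% of the
#' pool (inclusive). A frameshift single-majority call is either a PreMA
#' whose deletion length is not a multiple of 3, or any single-majority 1 bp
#' insertion.
#'
#' @param event A `repair_event`.
#' @return A list of class `truth_label` with `event_id`, `included`,
#'   `category`, `top_freq`, `is_prema`, `is_sm_insertion`,
#'   `is_sm_frameshift` and the underlying `indel_call` (or `NULL`).
#' @export
label_event <- function(event) {
  stopifnot(inherits(event, "repair_event"))
  call <- if (event$top_read == event$wt) NULL else
    align_simple_indel(event$wt, event$top_read)
  included <- !is.null(call)
  category <- if (included) call$category else NA_character_
  sm <- included && event$top_freq >= 0.5
  is_prema <- sm && identical(category, "MMEJ_del")
  is_sm_insertion <- sm && identical(category, "ins_1bp")
  is_sm_frameshift <- (is_prema && (call$length %% 3L) != 0L) || is_sm_insertion
  structure(list(
    event_id = event$event_id, included = included, category = category,
    top_freq = event$top_freq, is_prema = is_prema,
    is_sm_insertion = is_sm_insertion, is_sm_frameshift = is_sm_frameshift,
    indel_call = call
  ), class = "truth_label")
}

#' Label a list of events into a tidy table
#'
#' @param events List of `repair_event` objects (e.g. from [load_events()]).
#' @param genomic_only Drop events whose `genomic` curation flag is `FALSE`
#'   (default `TRUE`, mirroring the exclusion of artificial target
#'   sequences).
#' @return Data frame with one row per event: `event_id`, `included`,
#'   `category`, `top_freq`, `is_prema`, `is_sm_insertion`,
#'   `is_sm_frameshift`, `indel_len`.
#' @export
classify_events <- function(events, genomic_only = TRUE) {
  if (genomic_only) events <- Filter(function(e) isTRUE(e$genomic), events)
  rows <- lapply(events, function(e) {
    lab <- label_event(e)
    data.frame(
      event_id = lab$event_id, included = lab$included,
      category = if (is.na(lab$category)) NA_character_ else lab$category,
      top_freq = lab$top_freq, is_prema = lab$is_prema,
      is_sm_insertion = lab$is_sm_insertion,
      is_sm_frameshift = lab$is_sm_frameshift,
      indel_len = if (is.null(lab$indel_call)) NA_integer_ else lab$indel_call$length,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame()
  out
}

#' Best-effort importer for processed mutational-profile layouts
#'
#' Adapts externally distributed per-target mutation profiles onto the
#' canonical events schema. The expected layout is a reads table with columns
#' `target_id`, `sequence`, `reads` (one row per observed repair sequence,
#' replicates already pooled) plus a targets table with columns `target_id`,
#' `wt_sequence`, `cut_site` (0-based) and optionally `genomic`. This layout
#' is a documented assumption, not a guarantee: public archives of this kind
#' do not ship a formal schema, so the importer is isolated from the core
#' pipeline and validates what it reads.
#'
#' @param reads_path TSV of observed repair reads.
#' @param targets_path TSV of WT sequences and cut sites.
#' @return A list of `repair_event` objects (see [load_events()]).
#' @export
import_mutational_profiles <- function(reads_path, targets_path) {
  rd <- utils::read.delim(reads_path, stringsAsFactors = FALSE)
  tg <- utils::read.delim(targets_path, stringsAsFactors = FALSE)
  need_rd <- c("target_id", "sequence", "reads")
  need_tg <- c("target_id", "wt_sequence", "cut_site")
  if (!all(need_rd %in% names(rd)) || !all(need_tg %in% names(tg))) {
    stop("unrecognised profile layout: expected columns ",
         paste(need_rd, collapse = "/"), " and ",
         paste(need_tg, collapse = "/"), call. = FALSE)
  }
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  merged <- merge(rd, tg, by = "target_id")
  canon <- data.frame(
    event_id = merged$target_id, wt = merged$wt_sequence,
    cut_index = merged$cut_site, read_seq = merged$sequence,
    count = merged$reads,
    genomic = if ("genomic" %in% names(merged)) merged$genomic else TRUE,
    stringsAsFactors = FALSE
  )
  utils::write.table(canon, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  load_events(tmp)
}

#' @export
print.repair_event <- function(x, ...) {
  cat("Repair event ", x$event_id, ": ", nrow(x$reads),
      " distinct reads, ", x$total_reads, " total\n", sep = "")
  cat(sprintf("  top read frequency: %.3f\n", x$top_freq))
  invisible(x)
}
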