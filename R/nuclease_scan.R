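# PAM scanning and cut-site mapping for SpCas9 (NGG) and Cas12a (TTTV).
#
# SpCas9 cuts bluntly 3 bp 5' of its NGG PAM: plus-strand cut_index =
# pam_start - 3 (a minus-strand PAM, CCN on the plus strand at q, maps to
# cut_index = q + 6). Cas12a cuts in a 18/23 stagger 3' of its TTTV PAM; a
# single nominal blunt break 18 nt past the 4-nt PAM is used (the stagger
# midpoint), configurable via `cas12a_offset`.

#' Locate nuclease target sites (PAMs) and their cut positions
#'
#' Scans for every PAM occurrence (NGG for SpCas9; TTTV, V in {A,C,G}, for
#' Cas12a) whose implied cut position lies strictly inside the sequence.
#' Minus-strand sites are found by scanning the reverse complement and
#' reflecting coordinates, so plus/minus symmetry holds by construction.
#'
#' @param seq Uppercase ACGT string.
#' @param nuclease `"SpCas9"` or `"Cas12a"`.
#' @param both_strands Scan the minus strand too (default `TRUE`).
#' @param cas12a_offset Nominal distance (nt) from the 3' end of the Cas12a
#'   PAM to the break (default 18).
#' @return A `data.frame` of class `guide_sites` with columns `nuclease`,
#'   `strand` (`"+"`/`"-"`), `pam_start` (0-based plus-strand start of the
#'   PAM-occupied interval), `pam` (PAM sequence on the target strand) and
#'   `cut_index` (0-based plus-strand break position), sorted by `cut_index`.
#' @examples
#' find_guide_sites("CCATGCATGCAAGG", "SpCas9", both_strands = FALSE)
#' @export
find_guide_sites <- function(seq, nuclease = c("SpCas9", "Cas12a"),
                             both_strands = TRUE, cas12a_offset = 18L) {
  .assert_dna(seq)
  nuclease <- match.arg(nuclease)
  n <- nchar(seq)
  cas12a_offset <- as.integer(cas12a_offset)

  scan_one <- function(sq) {
    # plus-strand scan of `sq`; returns 0-based pam_start, cut, pam string
    s <- .chars(sq)
    m <- length(s)
    if (nuclease == "SpCas9") {
      if (m < 3L) return(NULL)
      idx <- which(s[2:(m - 1L)] == "G" & s[3:m] == "G")  # 1-based PAM starts
      if (length(idx) == 0L) return(NULL)
      p0 <- idx - 1L                       # 0-based pam_start
      cut <- p0 - 3L
      pam <- substring(sq, idx, idx + 2L)
    } else {
      if (m < 4L) return(NULL)
      idx <- which(s[1:(m - 3L)] == "T" & s[2:(m - 2L)] == "T" &
                   s[3:(m - 1L)] == "T" & s[4:m] != "T")
      if (length(idx) == 0L) return(NULL)
      p0 <- idx - 1L
      cut <- p0 + 4L + cas12a_offset
      pam <- substring(sq, idx, idx + 3L)
    }
    keep <- cut > 0L & cut < m
    if (!any(keep)) return(NULL)
    data.frame(pam_start = p0[keep], pam = pam[keep], cut_index = cut[keep],
               stringsAsFactors = FALSE)
  }

  pam_len <- if (nuclease == "SpCas9") 3L else 4L
  out <- list()
  plus <- scan_one(seq)
  if (!is.null(plus)) {
    plus$strand <- "+"
    out[[length(out) + 1L]] <- plus
  }
  if (isTRUE(both_strands)) {
    minus <- scan_one(revcomp(seq))
    if (!is.null(minus)) {
      # reflect revcomp coordinates back onto the plus strand
      minus <- data.frame(
        pam_start = n - (minus$pam_start + pam_len),
        pam = minus$pam,
        cut_index = n - minus$cut_index,
        strand = "-", stringsAsFactors = FALSE
      )
      out[[length(out) + 1L]] <- minus
    }
  }
  if (length(out) == 0L) {
    df <- data.frame(nuclease = character(0), strand = character(0),
                     pam_start = integer(0), pam = character(0),
                     cut_index = integer(0), stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, out)
    df$nuclease <- nuclease
    df <- df[order(df$cut_index, df$strand, df$pam_start),
             c("nuclease", "strand", "pam_start", "pam", "cut_index")]
    rownames(df) <- NULL
  }
  class(df) <- c("guide_sites", "data.frame")
  df
}

#' Extract a fixed-width sequence window centred at a cut
#'
#' Returns `seq[cut_index - width/2, cut_index + width/2)` (0-based,
#' half-open) so the break sits at the window midpoint. Sites whose window
#' would run past either sequence end are skipped: `NA_character_` is
#' returned rather than a truncated window.
#'
#' @param seq DNA string.
#' @param cut_index 0-based break position.
#' @param width Even window width; 52 (deletion scoring) and 60 (insertion
#'   predictors) are the conventional presets.
#' @return The window string, or `NA_character_` if out of bounds.
#' @export
extract_context <- function(seq, cut_index, width) {
  .assert_dna(seq)
  width <- as.integer(width)
  if (is.na(width) || width <= 0L || width %% 2L != 0L) {
    stop("`width` must be a positive even integer", call. = FALSE)
  }
  cut_index <- as.integer(cut_index)
  lo <- cut_index - width %/% 2L
  hi <- cut_index + width %/% 2L
  if (lo < 0L || hi > nchar(seq)) return(NA_character_)
  substr(seq, lo + 1L, hi)
}
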