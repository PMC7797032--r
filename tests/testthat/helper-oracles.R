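# Independent oracles and shared fixtures, written before and kept separate
# from the implementations they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force O(n^3) enumeration of cut-spanning microhomology patterns:
# every (left_start, right_start, lam) triple is tried via substring
# comparison (the lam loop breaks at the first mismatch, which cannot be
# undone by longer arms), then products are deduplicated keeping the
# maximal-lam representative.
oracle_mh <- function(context, cut, min_arm = 3L) {
  n <- nchar(context)
  rows <- list()
  for (i in 0:(n - 1L)) {
    for (j in (i + 1L):(n - 1L)) {
      if (j < cut || i + min_arm > cut) next
      lam_max <- min(j - i, n - j, cut - i)
      if (lam_max < min_arm) next
      for (lam in min_arm:lam_max) {
        if (substr(context, i + 1L, i + lam) !=
            substr(context, j + 1L, j + lam)) break
        rows[[length(rows) + 1L]] <- data.frame(
          left_start = i, right_start = j, lam = lam, dist = j - i - lam,
          del_len = j - i,
          arm_seq = substr(context, i + 1L, i + lam),
          product = paste0(substr(context, 1L, i),
                           substr(context, j + 1L, n)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  df <- do.call(rbind, rows)
  df <- df[order(df$product, -df$lam, df$dist, df$left_start), ]
  df <- df[!duplicated(df$product), ]
  df[order(df$left_start, df$right_start), ]
}

# Prefix/suffix arithmetic oracle for "read is WT plus exactly one
# contiguous indel, no substitutions", with leftmost placement.
oracle_single_indel <- function(wt, read) {
  if (wt == read) return(NULL)
  a <- strsplit(wt, "")[[1]]
  b <- strsplit(read, "")[[1]]
  m <- min(length(a), length(b))
  p <- 0L
  while (p < m && a[p + 1L] == b[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < m && a[length(a) - s] == b[length(b) - s]) s <- s + 1L
  if (length(a) == length(b) || p + s < m) return(NULL)
  d <- abs(length(a) - length(b))
  if (length(a) > length(b)) {
    list(kind = "deletion", length = d, left = max(0L, length(b) - s))
  } else {
    left <- max(0L, length(a) - s)
    list(kind = "insertion", length = d, left = left,
         inserted_seq = substr(read, left + 1L, left + d))
  }
}

# Labelled (score, dist) corpus whose truth is exactly the two-threshold
# PreMA rule, with features computed by the package on random windows.
make_rule_corpus <- function(n, seed) {
  set.seed(seed)
  feats <- t(vapply(seq_len(n), function(i) {
    ctx <- random_dna(60L)
    r <- menthu(ctx, 30L)
    c(score = r$menthu_score,
      dist = if (is.na(r$top_dist)) NA_real_ else as.numeric(r$top_dist))
  }, numeric(2)))
  df <- data.frame(score = feats[, 1], dist = feats[, 2])
  df <- df[!is.na(df$dist), , drop = FALSE]
  df$prema <- df$score >= 1.5 & df$dist <= 5
  rownames(df) <- NULL
  df
}
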