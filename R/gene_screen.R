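# Early coding-region knockout screening: find nuclease-targetable sites in
# the first 30% of a CDS (at least the first 182 bp = 150 + 32 bp of
# upstream prediction context for short genes) that are predicted to yield a
# single-majority frameshift, via an out-of-frame PreMA deletion or --
# when an insertion adapter is supplied -- a single-majority 1 bp insertion.

#' Screen the early coding region of one gene
#'
#' Scans the CDS for guide sites of the requested nucleases, keeps cuts
#' inside the screened span (`max(round(0.30 * cds_len), 182)`), scores each
#' with the microhomology engine on a window centred at the cut (52 nt, or
#' 60 nt when an insertion adapter is used), and reports whether any site is
#' predicted to yield a single-majority frameshift. Sites too close to a
#' sequence end for a full prediction window (or within 30 nt of the 3' end)
#' are skipped and counted.
#'
#' @param cds Uppercase ACGT coding sequence (from the start codon).
#' @param gene_id Identifier for reporting.
#' @param nucleases Character subset of `c("SpCas9", "Cas12a")`.
#' @param insertion_adapter Optional adapter function (see
#'   [mendel_predict()]); when supplied, sites are evaluated with the full
#'   MENdel call on 60-nt windows.
#' @param score_threshold,dist_threshold PreMA thresholds (defaults 1.50, 5).
#' @param min_arm Minimum arm length (default 3).
#' @param cas12a_offset Cas12a cut-offset convention (default 18).
#' @return A list of class `gene_screen_report`: `gene_id`, `cds_len`,
#'   `screened_span`, `unscreenable`, `sites` (data frame with per-site
#'   nuclease, strand, coordinates, MENTHU score, arm distance, deletion
#'   length, `is_prema`, `frameshift_site`), `n_skipped`,
#'   `has_early_frameshift_site` and `prema_site_fraction`.
#' @export
screen_gene <- function(cds, gene_id = "gene",
                        nucleases = c("SpCas9"),
                        insertion_adapter = NULL,
                        score_threshold = 1.5, dist_threshold = 5L,
                        min_arm = 3L, cas12a_offset = 18L) {
  .assert_dna(cds)
  nucleases <- match.arg(nucleases, c("SpCas9", "Cas12a"), several.ok = TRUE)
  n <- nchar(cds)
  span <- max(as.integer(round(0.30 * n)), 182L)
  width <- if (is.null(insertion_adapter)) 52L else 60L
  empty_sites <- data.frame(
    nuclease = character(0), strand = character(0), pam_start = integer(0),
    cut_index = integer(0), menthu_score = numeric(0), top_dist = integer(0),
    top_del_len = integer(0), is_prema = logical(0),
    frameshift_site = logical(0), stringsAsFactors = FALSE
  )
  if (n < 182L + 30L) {
    return(structure(list(
      gene_id = gene_id, cds_len = n, screened_span = span,
      unscreenable = TRUE, sites = empty_sites, n_skipped = 0L,
      has_early_frameshift_site = NA, prema_site_fraction = NA_real_
    ), class = "gene_screen_report"))
  }
  sites <- do.call(rbind, lapply(nucleases, function(nc) {
    find_guide_sites(cds, nc, both_strands = TRUE,
                     cas12a_offset = cas12a_offset)
  }))
  sites <- sites[sites$cut_index < span, , drop = FALSE]
  n_skipped <- 0L
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cut <- sites$cut_index[i]
    ctx <- extract_context(cds, cut, width)
    if (is.na(ctx) || n - cut < 30L) {     # insufficient prediction context
      n_skipped <- n_skipped + 1L
      next
    }
    if (is.null(insertion_adapter)) {
      res <- menthu(ctx, width %/% 2L, min_arm = min_arm,
                    score_threshold = score_threshold,
                    dist_threshold = dist_threshold)
      fs <- res$is_prema && isTRUE(res$top_frameshift)
    } else {
      mc <- mendel_predict(ctx, insertion_adapter,
                           score_threshold = score_threshold,
                           dist_threshold = dist_threshold)
      res <- mc$menthu
      fs <- mc$frameshift_call
    }
    rows[[i]] <- data.frame(
      nuclease = sites$nuclease[i], strand = sites$strand[i],
      pam_start = sites$pam_start[i], cut_index = cut,
      menthu_score = res$menthu_score,
      top_dist = if (is.na(res$top_dist)) NA_integer_ else res$top_dist,
      top_del_len = if (is.na(res$top_del_len)) NA_integer_ else res$top_del_len,
      is_prema = res$is_prema, frameshift_site = fs,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  site_df <- if (length(rows) > 0L) do.call(rbind, rows) else empty_sites
  rownames(site_df) <- NULL
  structure(list(
    gene_id = gene_id, cds_len = n, screened_span = span,
    unscreenable = FALSE, sites = site_df, n_skipped = n_skipped,
    has_early_frameshift_site = nrow(site_df) > 0L && any(site_df$frameshift_site),
    prema_site_fraction = if (nrow(site_df) > 0L) mean(site_df$is_prema)
      else NA_real_
  ), class = "gene_screen_report")
}

#' Screen a set of genes and summarise coverage
#'
#' @param cds_set Named character vector of CDS sequences, or a FASTA path.
#' @param ... Passed to [screen_gene()].
#' @return List with `reports` (per-gene `gene_screen_report`) and `summary`
#'   (data frame: per-gene site counts, PreMA fraction, frameshift-site
#'   flag) plus the overall fraction of screenable genes with at least one
#'   early frameshift site (`frac_genes_with_site`).
#' @export
screen_genes <- function(cds_set, ...) {
  if (is.character(cds_set) && length(cds_set) == 1L && file.exists(cds_set)) {
    cds_set <- .read_fasta(cds_set)
  }
  stopifnot(is.character(cds_set), length(cds_set) > 0L)
  if (is.null(names(cds_set))) {
    names(cds_set) <- paste0("gene", seq_along(cds_set))
  }
  reports <- lapply(names(cds_set), function(g) {
    screen_gene(cds_set[[g]], gene_id = g, ...)
  })
  summary <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      gene_id = r$gene_id, cds_len = r$cds_len,
      screened_span = r$screened_span, unscreenable = r$unscreenable,
      n_sites = nrow(r$sites), n_skipped = r$n_skipped,
      prema_site_fraction = r$prema_site_fraction,
      has_early_frameshift_site = r$has_early_frameshift_site,
      stringsAsFactors = FALSE
    )
  }))
  screenable <- summary[!summary$unscreenable, , drop = FALSE]
  list(reports = reports, summary = summary,
       frac_genes_with_site = if (nrow(screenable) > 0L)
         mean(screenable$has_early_frameshift_site) else NA_real_)
}

#' @export
print.gene_screen_report <- function(x, ...) {
  cat("Gene screen: ", x$gene_id, " (CDS ", x$cds_len, " nt, screened span ",
      x$screened_span, " nt)\n", sep = "")
  if (x$unscreenable) {
    cat("  CDS too short to screen (needs >= 212 nt)\n")
    return(invisible(x))
  }
  cat("  evaluated sites: ", nrow(x$sites), "  (skipped for context: ",
      x$n_skipped, ")\n", sep = "")
  cat(sprintf("  PreMA site fraction: %s\n",
              if (is.na(x$prema_site_fraction)) "NA"
              else sprintf("%.3f", x$prema_site_fraction)))
  cat("  early frameshift site present: ", x$has_early_frameshift_site,
      "\n", sep = "")
  invisible(x)
}
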