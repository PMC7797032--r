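# Seeded synthetic data with analytically known truth labels.
#
# plant_mh_sequence() builds a WT window containing exactly one
# microhomology arm pair (requested lambda/dist) straddling the cut. A
# uniformly random background will almost surely contain chance cut-spanning
# 3-mer repeats (hundreds of candidate pairs, each matching with probability
# 4^-3), so whole-sequence rejection cannot deliver uniqueness; instead the
# background is generated base by base under a forbidden-3-mer constraint:
# no 3-mer may occur both fully 5' and fully 3' of the cut except inside the
# planted arms, and single-base extensions of the arms are blocked so the
# planted arm length is exact. Attempts are bounded; failures restart the
# whole background. simulate_repair_pool() then draws a multinomial read
# pool over the planted MMEJ product, non-MMEJ deletions (junction homology
# < 3 enforced) and insertions, and reports the realised truth label
# alongside, so pipeline recovery can be checked read-for-read.

#' Simulation profile for a repair-read pool
#'
#' @param n_reads Total reads in the pool.
#' @param frac_mmej_top Fraction of reads given to the planted MMEJ product.
#' @param frac_nhej_del Fraction spread over random non-MMEJ deletions.
#' @param frac_ins1 Fraction given to a 1 bp insertion at the cut.
#' @param seed Integer seed.
#' @param frac_ins_multi Optional fraction given to a 2-3 bp insertion
#'   (default 0).
#' @return A list of class `sim_profile`. Fractions must sum to 1 within
#'   1e-9.
#' @export
sim_profile <- function(n_reads, frac_mmej_top, frac_nhej_del, frac_ins1,
                        seed, frac_ins_multi = 0) {
  fr <- c(frac_mmej_top, frac_nhej_del, frac_ins1, frac_ins_multi)
  stopifnot(n_reads >= 1, all(fr >= 0))
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("profile fractions must sum to 1 (got ", format(sum(fr)), ")",
         call. = FALSE)
  }
  structure(list(n_reads = as.integer(n_reads), frac_mmej_top = frac_mmej_top,
                 frac_nhej_del = frac_nhej_del, frac_ins1 = frac_ins1,
                 frac_ins_multi = frac_ins_multi, seed = as.integer(seed)),
            class = "sim_profile")
}

# Sample an arm of length lam with gc G/C bases and pairwise-distinct 3-mers.
.sample_arm <- function(lam, gc) {
  for (i in 1:200) {
    bases <- c(sample(c("G", "C"), gc, replace = TRUE),
               sample(c("A", "T"), lam - gc, replace = TRUE))
    arm <- sample(bases)
    if (lam < 5L) return(arm)
    kmers <- vapply(1:(lam - 2L),
                    function(j) paste(arm[j:(j + 2L)], collapse = ""),
                    character(1))
    if (!anyDuplicated(kmers)) return(arm)
  }
  stop("could not sample an arm without internal 3-mer repeats", call. = FALSE)
}

#' Plant a unique microhomology arm pair in a random background
#'
#' Generates a sequence of length `total_len` whose only microhomology
#' pattern (arm length >= 3, after product deduplication) straddling the cut
#' is the planted pair with the requested arm length, arm distance and arm GC
#' content. The cut sits at `total_len %/% 2`, inside (or abutting) the
#' spacer between the arms. Deterministic per seed.
#'
#' @param total_len Sequence length; must allow `2*lam + dist` plus 40 nt of
#'   background.
#' @param lam Arm length (>= 3).
#' @param dist Bases between the arms (>= 0).
#' @param gc_arm Target GC fraction of the arm (default 0.5).
#' @param seed Integer seed.
#' @param max_attempts Bound on background restarts (default 10000).
#' @return List with `sequence`, `cut_index` and `pattern` (a one-row
#'   `data.frame` with the planted `arm_seq`, `left_start`, `right_start`,
#'   `lam`, `dist`, `del_len`, `product`).
#' @export
plant_mh_sequence <- function(total_len, lam, dist, gc_arm = 0.5, seed,
                              max_attempts = 10000L) {
  total_len <- as.integer(total_len); lam <- as.integer(lam)
  dist <- as.integer(dist)
  stopifnot(lam >= 3L, dist >= 0L)
  if (total_len < 2L * lam + dist + 40L) {
    stop("total_len too short for the requested pattern plus background",
         call. = FALSE)
  }
  cut <- total_len %/% 2L
  left_end <- cut - dist %/% 2L          # 0-based end (exclusive) of left arm
  right_start <- left_end + dist
  left_start <- left_end - lam
  right_end <- right_start + lam
  stopifnot(left_start >= 1L, right_end <= total_len - 1L)
  gc <- as.integer(round(gc_arm * lam))
  is_arm_pos <- function(p) (p >= left_start && p < left_end) ||
    (p >= right_start && p < right_end)
  in_left_arm <- function(j) j >= left_start && j + 3L <= left_end
  in_right_arm <- function(j) j >= right_start && j + 3L <= right_end
  # the two positions where a single-base arm extension must be blocked,
  # each paired with the already-set position it must differ from
  ext1_pos <- if (dist >= 1L) right_start - 1L else left_start - 1L
  ext1_other <- if (dist >= 1L) left_start - 1L else right_start - 1L
  ext2_pos <- right_end
  ext2_other <- left_end

  .with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      arm <- .sample_arm(lam, gc)
      arm3 <- vapply(seq_len(lam - 2L),
                     function(j) paste(arm[j:(j + 2L)], collapse = ""),
                     character(1))
      s <- character(total_len)
      s[(left_start + 1L):left_end] <- arm
      s[(right_start + 1L):right_end] <- arm

      kmer_ok <- function(j) {
        # j: 0-based start of a fully determined 3-mer
        kmer <- paste(s[(j + 1L):(j + 3L)], collapse = "")
        if (j + 3L <= cut) {                   # fully 5' of the break
          !(kmer %in% arm3) || in_left_arm(j)
        } else if (j >= cut) {                 # fully 3' of the break
          in_right_arm(j) || !(kmer %in% lset || kmer %in% arm3)
        } else TRUE                            # straddles the break
      }

      lset <- character(0)
      ok <- TRUE
      for (pos in seq_len(total_len) - 1L) {   # 0-based, left to right
        cands <- if (is_arm_pos(pos)) s[pos + 1L] else sample(.DNA)
        placed <- FALSE
        for (b in cands) {
          s[pos + 1L] <- b
          good <- TRUE
          if (pos == ext1_pos && b == s[ext1_other + 1L]) good <- FALSE
          if (pos == ext2_pos && b == s[ext2_other + 1L]) good <- FALSE
          if (good) {
            for (j in max(0L, pos - 2L):pos) {
              if (j + 2L > total_len - 1L) next
              if (any(s[(j + 1L):(j + 3L)] == "")) next  # not yet determined
              if (!kmer_ok(j)) { good <- FALSE; break }
            }
          }
          if (good) { placed <- TRUE; break }
          if (!is_arm_pos(pos)) s[pos + 1L] <- ""
        }
        if (!placed) { ok <- FALSE; break }
        if (pos >= 2L && pos + 1L <= cut) {    # completed left-side 3-mer
          lset <- c(lset, paste(s[(pos - 1L):(pos + 1L)], collapse = ""))
        }
      }
      if (!ok) next
      seqn <- paste(s, collapse = "")
      pats <- enumerate_mh_patterns(seqn, cut, min_arm = 3L)
      if (nrow(pats) == 1L && pats$left_start == left_start &&
          pats$lam == lam && pats$dist == dist) {
        return(list(
          sequence = seqn, cut_index = cut,
          pattern = data.frame(
            arm_seq = paste(arm, collapse = ""), left_start = left_start,
            right_start = right_start, lam = lam, dist = dist,
            del_len = lam + dist,
            product = apply_deletion(seqn, left_start, lam + dist),
            stringsAsFactors = FALSE
          )
        ))
      }
    }
    stop("plant_mh_sequence: no admissible background after ", max_attempts,
         " attempts (total_len=", total_len, ", lam=", lam, ", dist=", dist,
         ")", call. = FALSE)
  })
}

# Sample a deletion read spanning the cut with junction homology < 3,
# distinct from `avoid` products.
.sample_nonmmej_deletion <- function(wt, cut, avoid, max_attempts = 500L) {
  n <- nchar(wt)
  for (i in seq_len(max_attempts)) {
    d <- sample(1:12, 1L)
    lo <- max(0L, cut - d); hi <- min(cut, n - d)
    if (lo > hi) next
    a <- sample(lo:hi, 1L)
    prod <- apply_deletion(wt, a, d)
    if (prod == wt || prod %in% avoid) next
    if (junction_microhomology(wt, a, d) < 3L) return(prod)
  }
  stop("could not sample a non-MMEJ deletion", call. = FALSE)
}

#' Simulate a repair-read pool with known truth
#'
#' Draws multinomial read counts over the planted MMEJ product, several
#' distinct non-MMEJ deletion products (junction homology < 3 enforced by
#' resampling), a 1 bp insertion at the cut, and optionally a 2-3 bp
#' insertion, according to `profile`. The truth label is computed from the
#' realised counts and the generator's knowledge of each read's category, so
#' [label_event()] on the returned event must reproduce it exactly.
#'
#' @param wt WT sequence containing a planted pattern spanning `cut_index`
#'   whenever `frac_mmej_top > 0`.
#' @param cut_index 0-based break position.
#' @param profile A [sim_profile()].
#' @param n_nhej Number of distinct non-MMEJ deletion products the NHEJ mass
#'   is spread over (default 5).
#' @return List with `event` (a `repair_event`) and `truth` (the realised
#'   label: `event_id`, `included`, `category`, `top_freq`, `is_prema`,
#'   `is_sm_insertion`, `is_sm_frameshift`).
#' @export
simulate_repair_pool <- function(wt, cut_index, profile, n_nhej = 5L) {
  stopifnot(inherits(profile, "sim_profile"))
  .assert_dna(wt)
  .with_seed(profile$seed, {
    reads <- character(0); probs <- numeric(0); cats <- character(0)
    mmej_len <- NA_integer_
    if (profile$frac_mmej_top > 0) {
      pats <- enumerate_mh_patterns(wt, cut_index, min_arm = 3L)
      if (nrow(pats) == 0L) {
        stop("wt has no MMEJ pattern spanning the cut but frac_mmej_top > 0",
             call. = FALSE)
      }
      top <- pats[order(-pats$score, pats$dist, pats$left_start), ][1L, ]
      reads <- c(reads, top$product); probs <- c(probs, profile$frac_mmej_top)
      cats <- c(cats, "MMEJ_del")
      mmej_len <- top$del_len
    }
    if (profile$frac_nhej_del > 0) {
      for (i in seq_len(n_nhej)) {
        prod <- .sample_nonmmej_deletion(wt, cut_index, reads)
        reads <- c(reads, prod)
        probs <- c(probs, profile$frac_nhej_del / n_nhej)
        cats <- c(cats, "nonMMEJ_del")
      }
    }
    if (profile$frac_ins1 > 0) {
      base <- sample(.DNA, 1L)
      reads <- c(reads, paste0(substr(wt, 1L, cut_index), base,
                               substr(wt, cut_index + 1L, nchar(wt))))
      probs <- c(probs, profile$frac_ins1)
      cats <- c(cats, "ins_1bp")
    }
    if (profile$frac_ins_multi > 0) {
      ins <- paste(sample(.DNA, sample(2:3, 1L), replace = TRUE),
                   collapse = "")
      reads <- c(reads, paste0(substr(wt, 1L, cut_index), ins,
                               substr(wt, cut_index + 1L, nchar(wt))))
      probs <- c(probs, profile$frac_ins_multi)
      cats <- c(cats, "ins_multi")
    }
    stopifnot(!anyDuplicated(reads))
    counts <- as.integer(stats::rmultinom(1L, profile$n_reads, probs))
    keep <- counts > 0L
    reads <- reads[keep]; counts <- counts[keep]; cats <- cats[keep]
    ord <- order(-counts, reads)                 # same tie-break as the pool
    reads <- reads[ord]; counts <- counts[ord]; cats <- cats[ord]
    ev <- repair_event(
      event_id = paste0("sim", profile$seed), wt = wt, cut_index = cut_index,
      reads = data.frame(seq = reads, count = counts, stringsAsFactors = FALSE)
    )
    top_cat <- cats[1L]
    top_freq <- counts[1L] / sum(counts)
    sm <- top_freq >= 0.5
    is_prema <- sm && top_cat == "MMEJ_del"
    is_sm_ins <- sm && top_cat == "ins_1bp"
    top_len <- if (top_cat == "MMEJ_del") mmej_len else
      abs(nchar(reads[1L]) - nchar(wt))
    truth <- list(
      event_id = ev$event_id, included = TRUE, category = top_cat,
      top_freq = top_freq, is_prema = is_prema, is_sm_insertion = is_sm_ins,
      is_sm_frameshift = (is_prema && (top_len %% 3L) != 0L) || is_sm_ins
    )
    list(event = ev, truth = truth)
  })
}

# Study-condition defaults for the labelled corpus: top-read category mix
# 54% non-MMEJ deletion / 31% MMEJ deletion / 14% 1 bp insertion / 0.2%
# longer insertion; PreMA prevalence is carved out of the MMEJ-top share;
# majority tops at U(0.55, 0.85) frequency, sub-majority tops at
# U(0.30, 0.48); arm length 3-8 (decaying), arm distance 0-10 with PreMA
# events favouring short distances.
.corpus_mix <- c(nonMMEJ = 0.54, MMEJ = 0.31, ins1 = 0.14, ins_multi = 0.002)

#' Simulate a labelled corpus in memory
#'
#' Generates `n_events` events (60-nt WT windows, cut at 30) whose top-read
#' category mix mirrors observed repair pools and whose PreMA prevalence is
#' `prema_prevalence`, each with its realised truth label.
#'
#' @param n_events Number of events (>= 1).
#' @param prema_prevalence Fraction of events that are true PreMAs
#'   (default 0.104).
#' @param seed Integer seed.
#' @param n_reads Reads per event (default 1000).
#' @return List with `events` (list of `repair_event`), `truth` (data
#'   frame) and `events_table` (canonical long-format rows).
#' @export
simulate_corpus <- function(n_events, prema_prevalence = 0.104, seed,
                            n_reads = 1000L) {
  stopifnot(n_events >= 1)
  mix <- .corpus_mix / sum(.corpus_mix)
  if (prema_prevalence > mix[["MMEJ"]]) {
    stop("prema_prevalence cannot exceed the MMEJ-top share (",
         round(mix[["MMEJ"]], 3), ")", call. = FALSE)
  }
  plan <- .with_seed(seed, {
    type <- sample(names(mix), n_events, replace = TRUE, prob = mix)
    p_major_mmej <- prema_prevalence / mix[["MMEJ"]]
    is_major <- stats::runif(n_events) < ifelse(
      type == "MMEJ", p_major_mmej,
      ifelse(type == "ins1", 186 / 826, 0))   # observed 1bp-ins majority share
    lam <- sample(3:8, n_events, replace = TRUE,
                  prob = c(0.35, 0.25, 0.18, 0.1, 0.07, 0.05))
    dist <- ifelse(type == "MMEJ" & is_major,
                   sample(0:8, n_events, replace = TRUE, prob = 0.65^(0:8)),
                   sample(0:10, n_events, replace = TRUE))
    # keep the planted pattern inside the 60-nt window with its 40-nt
    # background margin (2*lam + dist <= 20)
    dist <- pmin(dist, 20L - 2L * lam)
    data.frame(
      type = type, is_major = is_major, lam = lam, dist = dist,
      gc_arm = stats::runif(n_events, 0.25, 0.75),
      top_f = ifelse(is_major, stats::runif(n_events, 0.55, 0.85),
                     stats::runif(n_events, 0.30, 0.48)),
      ev_seed = sample.int(1073741824L, n_events),
      stringsAsFactors = FALSE
    )
  })
  events <- vector("list", n_events)
  truth_rows <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    pl <- plan[i, ]
    planted <- plant_mh_sequence(60L, pl$lam, pl$dist, pl$gc_arm,
                                 seed = pl$ev_seed)
    f <- pl$top_f; rest <- 1 - f
    fr <- switch(pl$type,
      MMEJ = c(mmej = f, nhej = rest * 0.8, ins1 = rest * 0.2, multi = 0),
      # non-MMEJ-top: the NHEJ mass is split over 5 reads, so keep the other
      # categories small enough that an NHEJ read stays on top
      nonMMEJ = c(mmej = 0.10, nhej = 0.82, ins1 = 0.08, multi = 0),
      ins1 = c(mmej = rest * 0.4, nhej = rest * 0.6, ins1 = f, multi = 0),
      ins_multi = c(mmej = 0, nhej = 1 - f, ins1 = 0, multi = f)
    )
    prof <- sim_profile(n_reads, fr[["mmej"]], fr[["nhej"]], fr[["ins1"]],
                        seed = pl$ev_seed + 1L, frac_ins_multi = fr[["multi"]])
    sim <- simulate_repair_pool(planted$sequence, planted$cut_index, prof)
    sim$event$event_id <- sprintf("ev%05d", i)
    sim$truth$event_id <- sim$event$event_id
    events[[i]] <- sim$event
    truth_rows[[i]] <- as.data.frame(sim$truth, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  events_table <- do.call(rbind, lapply(events, function(e) {
    data.frame(event_id = e$event_id, wt = e$wt, cut_index = e$cut_index,
               read_seq = e$reads$seq, count = e$reads$count, genomic = TRUE,
               stringsAsFactors = FALSE)
  }))
  list(events = events, truth = truth, events_table = events_table)
}

#' Simulate an evaluation corpus with natural microhomology competition
#'
#' [simulate_corpus()] plants windows whose cut-spanning microhomology
#' family is unique, which is ideal for checking label recovery but removes
#' the very signal a competition-based classifier uses: with a single
#' pattern, every score ratio is infinite. This generator instead draws
#' plain random 60-nt windows (which carry many competing arm pairs) and
#' emulates the competition hypothesis mechanistically: for events whose
#' top read is the best-scoring MMEJ deletion, the top-read frequency
#' follows a logistic link in `log(score ratio)` (capped at 20) and the arm
#' distance, with per-event noise, and the link's intercept is calibrated
#' so the fraction of majority (>= 0.5) MMEJ outcomes matches
#' `prema_prevalence`. Use this corpus to evaluate classifiers; measured
#' performance reflects that planted association, not repair biology.
#'
#' @inheritParams simulate_corpus
#' @return Same shape as [simulate_corpus()]: `events`, `truth`,
#'   `events_table`.
#' @export
simulate_eval_corpus <- function(n_events, prema_prevalence = 0.104, seed,
                                 n_reads = 1000L) {
  stopifnot(n_events >= 1)
  mix <- .corpus_mix / sum(.corpus_mix)
  if (prema_prevalence > mix[["MMEJ"]]) {
    stop("prema_prevalence cannot exceed the MMEJ-top share (",
         round(mix[["MMEJ"]], 3), ")", call. = FALSE)
  }
  plan <- .with_seed(seed, {
    type <- sample(names(mix), n_events, replace = TRUE, prob = mix)
    wt <- character(n_events)
    score <- numeric(n_events); dist <- integer(n_events)
    for (i in seq_len(n_events)) {
      repeat {   # windows without any cut-spanning pattern are vanishingly rare
        cand <- paste(sample(.DNA, 60L, replace = TRUE), collapse = "")
        r <- menthu(cand, 30L)
        if (!is.na(r$menthu_score)) {
          wt[i] <- cand
          score[i] <- r$menthu_score
          dist[i] <- r$top_dist
          break
        }
      }
    }
    # competition link: stronger, closer top patterns are likelier to
    # dominate the pool
    eta <- log(pmin(score, 20)) - 0.3 * dist + stats::rnorm(n_events, 0, 0.7)
    is_mmej <- type == "MMEJ"
    p_major_mmej <- prema_prevalence / mix[["MMEJ"]]
    q <- stats::quantile(eta[is_mmej], 1 - p_major_mmej, names = FALSE)
    f_mmej <- 0.5 + 0.35 * tanh((eta - q) / 2)
    is_major <- ifelse(is_mmej, f_mmej >= 0.5,
                       stats::runif(n_events) <
                         ifelse(type == "ins1", 186 / 826, 0))
    data.frame(
      type = type, wt = wt, is_major = is_major,
      top_f = ifelse(is_mmej, f_mmej,
                     ifelse(is_major, stats::runif(n_events, 0.55, 0.85),
                            stats::runif(n_events, 0.30, 0.48))),
      ev_seed = sample.int(1073741824L, n_events),
      stringsAsFactors = FALSE
    )
  })
  events <- vector("list", n_events)
  truth_rows <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    pl <- plan[i, ]
    f <- pl$top_f; rest <- 1 - f
    fr <- switch(pl$type,
      MMEJ = c(mmej = f, nhej = rest * 0.8, ins1 = rest * 0.2, multi = 0),
      nonMMEJ = c(mmej = 0.10, nhej = 0.82, ins1 = 0.08, multi = 0),
      ins1 = c(mmej = rest * 0.4, nhej = rest * 0.6, ins1 = f, multi = 0),
      ins_multi = c(mmej = 0, nhej = 1 - f, ins1 = 0, multi = f)
    )
    prof <- sim_profile(n_reads, fr[["mmej"]], fr[["nhej"]], fr[["ins1"]],
                        seed = pl$ev_seed + 1L, frac_ins_multi = fr[["multi"]])
    sim <- simulate_repair_pool(pl$wt, 30L, prof)
    sim$event$event_id <- sprintf("ev%05d", i)
    sim$truth$event_id <- sim$event$event_id
    events[[i]] <- sim$event
    truth_rows[[i]] <- as.data.frame(sim$truth, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  events_table <- do.call(rbind, lapply(events, function(e) {
    data.frame(event_id = e$event_id, wt = e$wt, cut_index = e$cut_index,
               read_seq = e$reads$seq, count = e$reads$count, genomic = TRUE,
               stringsAsFactors = FALSE)
  }))
  list(events = events, truth = truth, events_table = events_table)
}

#' Write a reproducible labelled synthetic corpus to disk
#'
#' Runs [simulate_corpus()] and writes the canonical events TSV plus a truth
#' TSV. Byte-identical for identical arguments.
#'
#' @inheritParams simulate_corpus
#' @param dir Output directory (created if needed); files `events.tsv` and
#'   `truth.tsv` are written there.
#' @return Invisibly, a list with `events_path`, `truth_path` and the truth
#'   data frame.
#' @export
write_corpus <- function(n_events, prema_prevalence = 0.104, seed, dir,
                         n_reads = 1000L) {
  corpus <- simulate_corpus(n_events, prema_prevalence, seed, n_reads)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  events_path <- file.path(dir, "events.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(corpus$events_table, events_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(events_path = events_path, truth_path = truth_path,
                 truth = corpus$truth))
}
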