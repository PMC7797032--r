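test_that("single-indel alignment calls the fixture deletion leftmost", {
  call <- align_simple_indel("AAGCATTTGCATCC", "AAGCATCC")
  expect_equal(call$kind, "deletion")
  expect_equal(call$length, 6L)
  expect_equal(call$left, 2L)       # ambiguous [2,8) vs [6,12): leftmost wins
  expect_equal(call$mh_len, 4L)
  expect_equal(call$category, "MMEJ_del")
})

test_that("identity, substitutions and multi-indel reads are excluded", {
  wt <- "AAGCATTTGCATCC"
  expect_null(align_simple_indel(wt, wt))
  expect_null(align_simple_indel(wt, "AAGCATTTGCATCG"))  # substitution only
  expect_null(align_simple_indel(wt, "AAGGATTGCATCC"))   # deletion + mismatch
  expect_null(align_simple_indel(wt, "AAGTATCC"))        # not one clean indel
  expect_error(align_simple_indel("", wt), "ACGT")
})

test_that("a 1 bp insertion is called with its inserted base", {
  call <- align_simple_indel("AAGCATTTGCATCC", "AAGCATTATGCATCC")
  expect_equal(call$kind, "insertion")
  expect_equal(call$length, 1L)
  expect_equal(call$inserted_seq, "A")
  expect_equal(call$category, "ins_1bp")
})

test_that("alignment calls agree with the prefix/suffix oracle on random indels", {
  set.seed(41)
  for (i in 1:60) {
    wt <- random_dna(sample(40:70, 1))
    n <- nchar(wt)
    if (i %% 2 == 0) {             # random deletion
      d <- sample(1:10, 1)
      a <- sample(0:(n - d), 1)
      read <- apply_deletion(wt, a, d)
    } else {                       # random insertion
      d <- sample(1:4, 1)
      a <- sample(0:n, 1)
      read <- paste0(substr(wt, 1, a), random_dna(d), substr(wt, a + 1, n))
    }
    if (read == wt) next
    got <- align_simple_indel(wt, read)
    want <- oracle_single_indel(wt, read)
    expect_false(is.null(got))
    expect_equal(got$kind, want$kind)
    expect_equal(got$length, want$length)
    expect_equal(got$left, want$left)
    # reconstructing the read from the call is exact
    rec <- if (got$kind == "deletion") apply_deletion(wt, got$left, got$length)
      else paste0(substr(wt, 1, got$left), got$inserted_seq,
                  substr(wt, got$left + 1, n))
    expect_identical(rec, read)
  }
})

test_that("junction microhomology measures the collapsed repeat", {
  expect_equal(junction_microhomology("AAGCATTTGCATCC", 2, 6), 4L)
  expect_lt(junction_microhomology("AAACGTGAC", 3, 2), 3L)
  expect_gte(junction_microhomology("AAAAAAAA", 2, 3), 3L)
  # placement invariance: equivalent intervals give the same k
  expect_equal(junction_microhomology("AAGCATTTGCATCC", 6, 6),
               junction_microhomology("AAGCATTTGCATCC", 2, 6))
  expect_error(junction_microhomology("ACGT", 2, 5), "bounds")
})

test_that("events load, consolidate and rank from the canonical TSV", {
  tsv <- file.path(tempdir(), "ev.tsv")
  df <- data.frame(
    event_id = c("e1", "e1", "e1", "e1"),
    wt = "AAGCATTTGCATCC", cut_index = 7L,
    read_seq = c("AAGCATCC", "AAGCTTGCATCC", "AAGCATCC", "AAGCATTGCATCC"),
    count = c(40L, 30L, 20L, 10L)
  )
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- load_events(tsv)
  expect_length(ev, 1L)
  e <- ev[[1]]
  expect_equal(e$total_reads, 100L)
  expect_equal(e$top_read, "AAGCATCC")       # duplicates summed: 60
  expect_equal(e$top_freq, 0.6)
  expect_equal(nrow(e$reads), 3L)

  # malformed rows are dropped with a warning naming their lines
  df$read_seq[2] <- "AAGCNTT"
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ev2 <- load_events(tsv), "line")
  expect_equal(ev2[[1]]$total_reads, 70L)

  # schema violations and empty files
  utils::write.table(df[, -1], tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_events(tsv), "event_id")
  utils::write.table(df[0, ], tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_warning(expect_length(load_events(tsv), 0L), "no rows")
})

test_that("event labels follow the majority and category rules", {
  wt <- "AAGCATTTGCATCC"
  mk <- function(counts, reads) {
    repair_event("e", wt, 7L, data.frame(seq = reads, count = counts))
  }
  # MMEJ deletion at 60%: PreMA, in-frame (del 6)
  lab <- label_event(mk(c(60, 25, 15), c("AAGCATCC", "AAGCATTTGCC", "AAGCATTTGCATC")))
  expect_true(lab$included)
  expect_equal(lab$category, "MMEJ_del")
  expect_true(lab$is_prema)
  expect_false(lab$is_sm_frameshift)
  # same top read below half the pool: no PreMA
  lab2 <- label_event(mk(c(45, 40, 15), c("AAGCATCC", "AAGCATTTGCC", "AAGCATTTGCATC")))
  expect_false(lab2$is_prema)
  expect_equal(lab2$category, "MMEJ_del")
  # majority 1 bp insertion: single-majority insertion, frameshift
  lab3 <- label_event(mk(c(55, 45), c("AAGCATTATGCATCC", "AAGCATCC")))
  expect_true(lab3$is_sm_insertion)
  expect_true(lab3$is_sm_frameshift)
  # WT top read: event excluded
  lab4 <- label_event(mk(c(70, 30), c(wt, "AAGCATCC")))
  expect_false(lab4$included)
  expect_false(lab4$is_prema)
})

test_that("category partition is exhaustive and exclusive over included events", {
  co <- simulate_corpus(60, 0.15, seed = 77)
  tab <- classify_events(co$events)
  inc <- tab[tab$included, ]
  expect_true(all(inc$category %in%
    c("MMEJ_del", "nonMMEJ_del", "ins_1bp", "ins_multi")))
  expect_false(any(tab$is_prema & tab$is_sm_insertion))
})

test_that("the profile importer adapts the external layout onto the schema", {
  reads <- file.path(tempdir(), "profiles.tsv")
  targets <- file.path(tempdir(), "targets.tsv")
  utils::write.table(
    data.frame(target_id = "t1", sequence = c("AAGCATCC", "AAGCATTGCATCC"),
               reads = c(60L, 40L)),
    reads, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(target_id = "t1", wt_sequence = "AAGCATTTGCATCC",
               cut_site = 7L),
    targets, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- import_mutational_profiles(reads, targets)
  expect_length(ev, 1L)
  expect_true(label_event(ev[[1]])$is_prema)
  expect_error(import_mutational_profiles(targets, targets), "layout")
})
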