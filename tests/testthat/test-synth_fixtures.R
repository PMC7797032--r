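test_that("planted arm pairs are unique, exact and deterministic", {
  pl <- plant_mh_sequence(60, 4, 2, 0.5, seed = 7)
  pats <- enumerate_mh_patterns(pl$sequence, pl$cut_index)
  expect_equal(nrow(pats), 1L)
  expect_equal(pats$lam, 4L)
  expect_equal(pats$dist, 2L)
  expect_equal(pats$left_start, pl$pattern$left_start)
  expect_equal(pats$product, pl$pattern$product)
  expect_identical(pl, plant_mh_sequence(60, 4, 2, 0.5, seed = 7))
  expect_false(identical(pl$sequence,
                         plant_mh_sequence(60, 4, 2, 0.5, seed = 8)$sequence))
})

test_that("planted deletion length follows lam + dist", {
  pl <- plant_mh_sequence(60, 3, 0, 0.5, seed = 5)
  expect_equal(pl$pattern$del_len, 3L)          # in-frame: 3 mod 3 == 0
  expect_equal(nchar(pl$pattern$product), 57L)
  expect_error(plant_mh_sequence(30, 8, 10, 0.5, seed = 1), "too short")
})

test_that("planting covers the parameter range used by the corpus", {
  set.seed(91)
  for (i in 1:25) {
    lam <- sample(3:8, 1)
    d <- sample(0:min(10, 20 - 2 * lam), 1)
    pl <- plant_mh_sequence(60, lam, d, runif(1, 0.25, 0.75), seed = 1000 + i)
    pats <- enumerate_mh_patterns(pl$sequence, pl$cut_index)
    expect_equal(nrow(pats), 1L)
    expect_equal(pats$lam, lam)
    expect_equal(pats$dist, d)
  }
})

test_that("profile fractions must sum to one", {
  expect_error(sim_profile(100, 0.5, 0.4, 0.2, seed = 1), "sum to 1")
  expect_silent(sim_profile(100, 0.5, 0.4, 0.1, seed = 1))
})

test_that("simulated pools realise the intended majority structure", {
  pl <- plant_mh_sequence(60, 4, 2, 0.5, seed = 7)
  s1 <- simulate_repair_pool(pl$sequence, pl$cut_index,
                             sim_profile(1000, 0.6, 0.3, 0.1, seed = 11))
  expect_true(s1$truth$is_prema)
  s2 <- simulate_repair_pool(pl$sequence, pl$cut_index,
                             sim_profile(1000, 0.45, 0.45, 0.1, seed = 11))
  expect_false(s2$truth$is_prema)
  s3 <- simulate_repair_pool(pl$sequence, pl$cut_index,
                             sim_profile(1000, 0, 0.2, 0.8, seed = 11))
  expect_true(s3$truth$is_sm_insertion)
  expect_true(s3$truth$is_sm_frameshift)
})

test_that("pipeline labels recover generator truth across seeded trials", {
  set.seed(92)
  for (i in 1:40) {
    lam <- sample(3:6, 1)
    d <- sample(0:6, 1)
    pl <- plant_mh_sequence(60, lam, d, 0.5, seed = 2000 + i)
    fr <- c(runif(1, 0.2, 0.7), runif(1, 0.1, 0.2), runif(1, 0.05, 0.15))
    fr <- c(fr, 0)
    fr <- fr / sum(fr)
    sim <- simulate_repair_pool(pl$sequence, pl$cut_index,
                                sim_profile(800, fr[1], fr[2], fr[3],
                                            seed = 3000 + i))
    lab <- label_event(sim$event)
    expect_identical(lab$included, sim$truth$included)
    expect_identical(lab$category, sim$truth$category)
    expect_identical(lab$is_prema, sim$truth$is_prema)
    expect_identical(lab$is_sm_insertion, sim$truth$is_sm_insertion)
    expect_identical(lab$is_sm_frameshift, sim$truth$is_sm_frameshift)
  }
})

test_that("sampled non-MMEJ deletions never carry junction homology >= 3", {
  pl <- plant_mh_sequence(60, 4, 1, 0.5, seed = 13)
  sim <- simulate_repair_pool(pl$sequence, pl$cut_index,
                              sim_profile(2000, 0.3, 0.6, 0.1, seed = 17))
  for (sq in sim$event$reads$seq) {
    call <- align_simple_indel(sim$event$wt, sq)
    if (!is.null(call) && call$kind == "deletion" &&
        sq != pl$pattern$product) {
      expect_lt(call$mh_len, 3L)
    }
  }
})

test_that("the evaluation corpus keeps natural competition and the target prevalence", {
  co <- simulate_eval_corpus(300, prema_prevalence = 0.104, seed = 93)
  # labels still recover exactly through the pipeline
  tab <- classify_events(co$events)
  tab <- tab[match(co$truth$event_id, tab$event_id), ]
  expect_equal(tab$is_prema, co$truth$is_prema)
  expect_equal(tab$category, co$truth$category)
  # prevalence is calibrated, up to multinomial noise at the majority boundary
  expect_lt(abs(mean(co$truth$is_prema) - 0.104), 0.04)
  # windows carry competing patterns: finite score ratios dominate
  scores <- vapply(co$events, function(e) menthu(e$wt, 30)$menthu_score,
                   numeric(1))
  expect_gt(mean(is.finite(scores)), 0.9)
  # the planted competition link makes the score informative where the
  # distance filter allows calls at all (the truncated-curve AUC itself is
  # small by construction: it covers only the attainable FPR range)
  dists <- vapply(co$events, function(e) menthu(e$wt, 30)$top_dist,
                  integer(1))
  el <- dists <= 5
  r <- roc_sweep(co$truth$is_prema[el], pmin(unname(scores[el]), 1e6),
                 mode = "probability_sweep")
  expect_gt(r$auc, 0.5)
  expect_identical(co$truth,
                   simulate_eval_corpus(300, 0.104, seed = 93)$truth)
})

test_that("corpus files are reproducible and round-trip through the pipeline", {
  d1 <- file.path(tempdir(), "corp1"); d2 <- file.path(tempdir(), "corp2")
  c1 <- write_corpus(60, prema_prevalence = 0.15, seed = 3, dir = d1)
  c2 <- write_corpus(60, prema_prevalence = 0.15, seed = 3, dir = d2)
  expect_identical(readLines(c1$events_path), readLines(c2$events_path))
  expect_identical(readLines(c1$truth_path), readLines(c2$truth_path))

  ev <- load_events(c1$events_path)
  tab <- classify_events(ev)
  truth <- utils::read.delim(c1$truth_path)
  tab <- tab[match(truth$event_id, tab$event_id), ]
  expect_equal(tab$is_prema, truth$is_prema)
  expect_equal(tab$is_sm_insertion, truth$is_sm_insertion)
  expect_equal(tab$is_sm_frameshift, truth$is_sm_frameshift)
  expect_equal(tab$category, truth$category)

  # zero prevalence yields no PreMA labels
  c0 <- write_corpus(25, prema_prevalence = 0, seed = 4,
                     dir = file.path(tempdir(), "corp0"))
  expect_false(any(c0$truth$is_prema))
})
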