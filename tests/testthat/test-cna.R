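mk_samples <- function(ids, sex) {
  validate_sample_sheet(data.frame(
    sample_id = ids, sex = sex, grade = "1a", invasive = FALSE,
    era_ir_score = NA_integer_, tumor_size_mm = NA_real_,
    clinical_behavior = "", stringsAsFactors = FALSE))
}

test_that("copy estimation scales the tumor/reference ratio by sex baseline", {
  probes <- data.frame(probe_id = sprintf("p%d", 1:6),
                       chromosome = c("1", "1", "X", "X", "Y", "Y"),
                       position = c(1e6, 2e6, 1e6, 2e6, 1e6, 2e6),
                       stringsAsFactors = FALSE)
  ref <- rep(100, 6)
  tum <- matrix(100, 6, 2, dimnames = list(probes$probe_id, c("SM", "SF")))
  samples <- mk_samples(c("SM", "SF"), c("M", "F"))
  cp <- estimate_copies(tum, ref, probes, samples)
  expect_equal(unname(cp$copies[1:2, "SM"]), c(2, 2))  # autosome, tumor = ref
  expect_equal(unname(cp$copies[3:4, "SM"]), c(1, 1))  # male X baseline
  expect_equal(unname(cp$copies[3:4, "SF"]), c(2, 2))
  expect_true(all(is.na(cp$copies[5:6, "SF"])))        # female Y excluded
  expect_equal(attr(cp, "n_excluded_female_y"), 2L)

  tum2 <- tum; tum2[1:2, "SM"] <- 200                  # doubled on one region
  cp2 <- estimate_copies(tum2, ref, probes, samples)
  expect_equal(unname(cp2$copies[1:2, "SM"]), c(4, 4))

  expect_error(estimate_copies(tum[1:3, ], ref, probes, samples), "mismatch")
  expect_error(estimate_copies(tum, rep(0, 6), probes, samples), "positive")
})

test_that("changepoint DP finds exact flat and step solutions", {
  flat <- segment_profile(rep(2, 30))
  expect_equal(nrow(flat), 1)
  expect_equal(flat$mean_copies, 2)

  x <- c(rep(2, 50), rep(4, 50))
  seg <- segment_profile(x, penalty = 1)  # far below the step's SSE saving
  expect_equal(nrow(seg), 2)
  expect_equal(seg$end_idx[1], 50)
  expect_equal(seg$mean_copies, c(2, 4))

  expect_error(segment_profile(c(1, 2), positions = c(5, 5)), "sorted")
  expect_error(segment_profile(numeric(0)), "empty")
})

test_that("DP matches exhaustive changepoint search on small noisy instances", {
  withr::with_seed(11, {
    for (rep in 1:12) {
      n <- sample(10:50, 1)
      k <- sample(0:2, 1)
      bounds <- sort(sample(4:(n - 4), k))
      levels <- cumsum(c(2, runif(k, -1.5, 1.5)))
      x <- numeric(n)
      prev <- 1
      for (j in seq_len(k + 1)) {
        to <- if (j <= k) bounds[j] else n
        x[prev:to] <- levels[j]
        prev <- to + 1
      }
      x <- x + rnorm(n, 0, 0.3)
      pen <- lactodim:::default_penalty(x)
      dp <- segment_profile(x, penalty = pen)
      if (nrow(dp) <= 3) {
        bf <- brute_force_segment(x, pen)
        expect_equal(segment_cost(x, dp, pen), bf$cost, tolerance = 1e-9)
        expect_equal(dp$start_idx, bf$bounds)
      }
    }
  })
})

test_that("penalty monotonicity: larger penalty never increases segment count", {
  withr::with_seed(3, {
    x <- c(rep(2, 40), rep(3.2, 30), rep(1.6, 30)) + rnorm(100, 0, 0.3)
  })
  pens <- c(0.1, 0.5, 2, 8, 32, 128)
  counts <- vapply(pens, function(p) nrow(segment_profile(x, penalty = p)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted breakpoints are recovered within two probes", {
  hits <- 0
  for (s in 1:100) {
    withr::with_seed(s, {
      x <- c(rep(2, 20), rep(3.2, 20)) + rnorm(40, 0, 0.3)
    })
    seg <- segment_profile(x)
    bp <- seg$end_idx[-nrow(seg)]
    if (length(bp) && any(abs(bp - 20) <= 2)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("gain/loss calling uses strict fixed cutoffs scaled by baseline", {
  segs <- data.frame(sample_id = "S", chromosome = c("1", "1", "1", "1", "X"),
                     arm_label = "q", start = 1:5, end = 2:6, n_probes = 3,
                     mean_copies = c(3.1, 1.2, 2.0, 2.7, 1.4),
                     baseline = c(2, 2, 2, 2, 1), stringsAsFactors = FALSE)
  called <- call_segments(segs)
  expect_equal(called$call, c("gain", "loss", "neutral", "neutral", "gain"))
  # male X gain cutoff is 1.35; idempotent; depends only on mean and baseline
  expect_equal(call_segments(called)$call, called$call)
  expect_error(call_segments(segs, gain_cutoff = 1.2, loss_cutoff = 2.5),
               "cutoffs")
})

test_that("recurrence counts deduplicate per sample and validate ids", {
  ev <- rbind(parse_event_tokens("S1", c("19p", "19p", "11"), "gain"),
              parse_event_tokens("S2", c("11"), "loss"),
              parse_event_tokens("S2", c("11p"), "loss"))
  samples <- mk_samples(c("S1", "S2", "S3"), c("M", "M", "F"))
  r <- count_recurrence(ev, samples, rep(TRUE, 3), "19", "p", "gain")
  expect_equal(r$count, 1)         # duplicated token counts once
  expect_equal(r$denominator, 3)
  # arm-level query matched by whole-chromosome events
  r2 <- count_recurrence(ev, samples, rep(TRUE, 3), "11", "q", "loss")
  expect_equal(r2$count, 1)
  r3 <- count_recurrence(ev, samples, rep(TRUE, 3), "11", NULL, "loss")
  expect_equal(r3$count, 1)

  none <- count_recurrence(ev[0, ], samples, rep(TRUE, 3), "1", NULL, "gain")
  expect_equal(none$count, 0)

  bad <- parse_event_tokens("GHOST", "1p", "gain")
  expect_error(count_recurrence(bad, samples, rep(TRUE, 3), "1", NULL, "gain"),
               "unknown sample")
})

test_that("segment events feed group recurrence summaries", {
  cfg <- small_config(seed = 4)
  co <- simulate_cohort(cfg)
  cp <- simulate_cna_profiles(cfg, co)
  segs <- call_segments(segment_profiles(cp, co))
  ev <- segments_to_events(segs)
  g <- count_recurrence(ev, co, aggressive_male, "19", "p", "gain")
  expect_equal(g$count, g$denominator)  # planted in every aggressive male
  females <- co$sex == "F"
  gf <- count_recurrence(ev, co, females & !aggressive(co), "19", "p", "gain")
  expect_equal(gf$count, 0)
  l <- count_recurrence(ev, co, aggressive, "11", NULL, "loss")
  expect_equal(l$count, sum(aggressive(co)) - 1)  # planted in all but one

  rec <- recurrence_by_group(ev, co,
                             list(aggressive_male = aggressive_male),
                             level = "arm")
  row <- rec[rec$chromosome == "19" & rec$arm == "p" & rec$event == "gain", ]
  expect_equal(row$count, g$count)
})
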