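# Window scan, null thresholds and candidate-region calling.

toy_records <- function(pos, delta, depth = 100L, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = pos, delta = delta,
                 depth_st = depth, depth_pl = depth)
}

test_that("constant per-site delta gives constant window means", {
  withr::with_seed(1, pos <- sort(sample.int(1e5, 60)))
  w <- sliding_windows(toy_records(pos, rep(0.42, 60)), 1e4, 1e3)
  expect_true(all(abs(w$mean_delta - 0.42) < 1e-12))
})

test_that("window means match a brute-force per-window average", {
  withr::with_seed(2, {
    pos <- sort(sample.int(1e5, 50))
    delta <- runif(50, -1, 1)
    depth_st <- rpois(50, 80)
    depth_pl <- rpois(50, 80)
  })
  rec <- tibble::tibble(chrom = "chr1", pos = pos, delta = delta,
                        depth_st = depth_st, depth_pl = depth_pl)
  w <- sliding_windows(rec, 1e4, 1e3)
  # oracle: loop over every possible window and average directly
  for (start in seq(0, 99000, by = 1000)) {
    inside <- pos > start & pos <= start + 1e4
    row <- w[w$start == start, ]
    if (!any(inside)) {
      expect_equal(nrow(row), 0)
    } else {
      expect_equal(row$n_sites, sum(inside))
      expect_equal(row$mean_delta, mean(delta[inside]))
      expect_equal(row$mean_depth, mean(pmin(depth_st, depth_pl)[inside]))
    }
  }
  expect_error(sliding_windows(rec, 100, 1000), "window_bp")
})

test_that("the causal window mean approaches the expected 2/3", {
  pop <- simulate_f2_population(toy_genome(len = 2e6, spacing = 2e4),
                                toy_cross(causal_pos = 1e6, n_f2 = 400,
                                          depth_mean = 500, seed = 14))
  b <- make_bulks(pop)
  rec <- passing_records(
    apply_site_filters(compute_snp_index(simulate_bulk_depths(pop, b)))
  )
  w <- sliding_windows(rec, 2e5, 1e4)
  causal_win <- w[w$chrom == "chr1" & w$start < 1e6 & w$end >= 1e6, ]
  expect_gt(nrow(causal_win), 0)
  # window means mix the causal site with partially linked neighbours and
  # one bulk draw; 0.1 covers the bulk-composition spread
  expect_lt(max(abs(causal_win$mean_delta - 2 / 3)), 0.15)
})

test_that("null thresholds collapse to the median at confidence zero", {
  c0 <- simulate_null_thresholds(15, 100, n_sim = 500, confidence = 0, seed = 3)
  expect_equal(c0$lower, c0$upper)
})

test_that("null thresholds shrink with depth and honor their confidence", {
  shrinks <- vapply(1:5, function(s) {
    cv <- simulate_null_thresholds(15, c(20, 200), n_sim = 2000, seed = s)
    cv$upper[cv$depth == 200] <= cv$upper[cv$depth == 20]
  }, logical(1))
  expect_gte(mean(shrinks), 0.8)

  # fresh null draws exceed the upper bound at about (1 - confidence) / 2
  cv <- simulate_null_thresholds(15, 100, n_sim = 4000, confidence = 0.95, seed = 7)
  withr::with_seed(123, {
    f1 <- rbinom(20000, 30, 0.5) / 30
    f2 <- rbinom(20000, 30, 0.5) / 30
    delta <- rbinom(20000, 100, f1) / 100 - rbinom(20000, 100, f2) / 100
  })
  rate <- mean(delta > cv$upper)
  expect_lt(abs(rate - 0.025), 3 * sqrt(0.025 * 0.975 / 20000) + 0.01)
})

test_that("region calling finds nothing on a flat track", {
  withr::with_seed(4, pos <- sort(sample.int(1e5, 80)))
  w <- sliding_windows(toy_records(pos, rep(0, 80)), 1e4, 1e3)
  scan <- call_candidate_regions(w, fixed_curve(0.3), step_bp = 1e3)
  expect_equal(nrow(scan$regions), 0)
})

test_that("two separated spikes give two regions with enumerated bounds", {
  # sites every 1 kb on a 50 kb chromosome; windows of 5 kb, step 1 kb
  pos <- seq(1000, 50000, by = 1000)
  delta <- rep(0, length(pos))
  delta[pos >= 10000 & pos <= 14000] <- 0.9   # spike 1
  delta[pos >= 30000 & pos <= 34000] <- 0.9   # spike 2
  w <- sliding_windows(toy_records(pos, delta), 5e3, 1e3)
  scan <- call_candidate_regions(w, fixed_curve(0.5), step_bp = 1e3, max_gap = 0)
  # oracle: a 5 kb window (start, start+5000] is significant iff the mean of
  # its five sites exceeds 0.5, i.e. >= 3 spike sites inside
  sig_starts <- vapply(seq(0, 45000, by = 1000), function(s) {
    inside <- pos > s & pos <= s + 5000
    mean(delta[inside]) > 0.5
  }, logical(1))
  starts <- seq(0, 45000, by = 1000)[sig_starts]
  runs <- split(starts, cumsum(c(1, diff(starts) != 1000)))
  expect_equal(nrow(scan$regions), length(runs))
  byl <- dplyr::arrange(scan$regions, start)
  for (k in seq_along(runs)) {
    expect_equal(byl$start[k], min(runs[[k]]))
    expect_equal(byl$end[k], max(runs[[k]]) + 5000)
  }
})

test_that("significant windows all fall inside called regions and vice versa", {
  pop <- simulate_f2_population(toy_genome(len = 5e6, spacing = 2e4),
                                toy_cross(causal_pos = 2.5e6, n_f2 = 395,
                                          error_rate = 0.001, seed = 15))
  b <- make_bulks(pop)
  rec <- passing_records(
    apply_site_filters(compute_snp_index(simulate_bulk_depths(pop, b)))
  )
  w <- sliding_windows(rec, 5e5, 1e4)
  curve <- simulate_null_thresholds(15, round(mean(w$mean_depth)), n_sim = 1000, seed = 16)
  scan <- call_candidate_regions(w, curve, step_bp = 1e4)
  sig <- scan$windows[scan$windows$significant, ]
  if (nrow(sig)) {
    in_region <- vapply(seq_len(nrow(sig)), function(i) {
      any(scan$regions$chrom == sig$chrom[i] &
            scan$regions$start <= sig$start[i] &
            scan$regions$end >= sig$end[i])
    }, logical(1))
    expect_true(all(in_region))
  }
  # each region holds at least one significant window and its peak
  for (i in seq_len(nrow(scan$regions))) {
    inside <- sig$chrom == scan$regions$chrom[i] &
      sig$start >= scan$regions$start[i] & sig$end <= scan$regions$end[i]
    expect_gt(sum(inside), 0)
    expect_equal(max(sig$mean_delta[inside]), scan$regions$peak_delta[i])
  }
  # and the top region contains the causal locus for this construction
  expect_equal(scan$regions$chrom[1], "chr1")
  expect_lte(scan$regions$start[1], 2.5e6 - 1)
  expect_gte(scan$regions$end[1], 2.5e6)
})

test_that("interval lengths in kb match direct arithmetic", {
  iv <- interval_from_1based("Pp03", 20839173, 20998220)
  expect_equal(interval_length_kb(iv), 159)
  expect_equal(interval_length_kb(tibble::tibble(start = 4000, end = 5000)), 1)
  withr::with_seed(6, {
    start <- sample.int(1e7, 10)
    len <- sample.int(1e6, 10)
  })
  iv2 <- tibble::tibble(start = start, end = start + len)
  expect_equal(interval_length_kb(iv2), round(len / 1000))
})
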