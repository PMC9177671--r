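test_that("SNP-index and delta follow their definitions", {
  expect_equal(snp_index(0, 12), 0)
  expect_equal(snp_index(12, 12), 1)
  expect_equal(snp_index(3, 12), 0.25)
  expect_true(is.na(snp_index(0, 0)))
  expect_error(snp_index(5, 3))
  expect_equal(delta_snp_index(0, 1), -1)
  expect_equal(delta_snp_index(1, 0), 1)
  x <- runif(20)
  expect_equal(delta_snp_index(x, x), rep(0, 20))
})

test_that("indices stay in [0,1] and delta in [-1,1] on random counts", {
  rec <- random_records(500, seed = 2)
  expect_true(all(rec$snp_index_high >= 0 & rec$snp_index_high <= 1,
                  na.rm = TRUE))
  expect_true(all(rec$delta >= -1 & rec$delta <= 1, na.rm = TRUE))
})

test_that("site filters remove exactly the hand-enumerated violators", {
  # six constructed sites:
  # 1: idx 0/0 @ 6/6        -> LOW_DEPTH and both-bulks LOW_INDEX
  # 2: idx 0/1 @ 6/20       -> LOW_DEPTH under the strict default only
  # 3: idx .20/.25 @ 20/20  -> LOW_INDEX (both below 0.3), het in both
  # 4: idx 0/1 @ 15/15      -> clean, causal-eligible
  # 5: idx .5/.5 @ 20/20    -> NOT_HOMOZYGOUS
  # 6: idx .2/1 @ 20/20     -> passes index rule (one bulk low only) but het
  sites <- toy_sites(
    high_ref = c(6L, 6L, 16L, 15L, 10L, 16L),
    high_alt = c(0L, 0L, 4L, 0L, 10L, 4L),
    low_ref  = c(6L, 0L, 15L, 0L, 10L, 0L),
    low_alt  = c(0L, 20L, 5L, 15L, 10L, 20L))
  rec <- apply_site_filters(compute_snp_indices(sites))
  expect_equal(rec$pass, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(rec$filter_flags[1], "LOW_DEPTH,LOW_INDEX")
  expect_equal(rec$filter_flags[2], "LOW_DEPTH")
  expect_equal(rec$filter_flags[3], "LOW_INDEX,NOT_HOMOZYGOUS")
  expect_equal(rec$filter_flags[4], "")
  expect_equal(rec$filter_flags[5], "NOT_HOMOZYGOUS")
  expect_equal(rec$filter_flags[6], "NOT_HOMOZYGOUS")
  # literal readings: site 2 survives the depth rule, site 4 dies to the
  # either-bulk index rule (it deletes every delta = -1 site)
  lit <- apply_site_filters(compute_snp_indices(sites),
                            depth_rule = "require_either",
                            index_rule = "either_below")
  expect_false(grepl("LOW_DEPTH", lit$filter_flags[2]))
  expect_match(lit$filter_flags[4], "LOW_INDEX")
  # filtering never mutates counts and only flags, never drops rows
  expect_equal(rec$high_alt, sites$high_alt)
  expect_equal(nrow(rec), nrow(sites))
})

test_that("filters are order-invariant and depth->index->zygosity order-free", {
  rec <- random_records(300, seed = 8)
  f1 <- apply_site_filters(rec)
  perm <- sample(nrow(rec))
  f2 <- apply_site_filters(rec[perm, ])
  expect_equal(f2$pass[order(perm)], f1$pass)
  expect_equal(f2$filter_flags[order(perm)], f1$filter_flags)
})

test_that("causal flagging requires a clean site with delta exactly -1", {
  sites <- toy_sites(
    high_ref = c(15L, 10L, 14L, 6L),
    high_alt = c(0L, 10L, 0L, 0L),
    low_ref  = c(0L, 10L, 7L, 0L),
    low_alt  = c(15L, 10L, 7L, 15L))
  rec <- flag_causal(apply_site_filters(compute_snp_indices(sites)))
  # site 1: (0,1) clean -> causal; site 2: delta 0 -> no; site 3: delta
  # -0.5 het -> no; site 4: delta -1 but LOW_DEPTH -> no
  expect_equal(rec$causal_flag, c(TRUE, FALSE, FALSE, FALSE))
  # the +1 orientation is flaggable via mode = "abs"
  swapped <- toy_sites(high_ref = 0L, high_alt = 15L,
                       low_ref = 15L, low_alt = 0L)
  rs <- flag_causal(apply_site_filters(compute_snp_indices(swapped)),
                    mode = "abs")
  expect_true(rs$causal_flag)
})

test_that("flagged causal sites equal a brute-force rescan on simulated data", {
  run <- run_fast_scan(77, n_markers = 400L)
  rec <- run$records
  brute <- rec$snp_index_high == 0 & rec$snp_index_low == 1 &
    rec$depth_high >= 7 & rec$depth_low >= 7
  brute[is.na(brute)] <- FALSE
  expect_identical(rec$causal_flag, unname(brute))
  # causal sites cluster around the planted QTL
  if (any(rec$causal_flag)) {
    qpos <- run$sim$truth$qtl[[1]]$causal_pos
    expect_lt(median(abs(rec$pos[rec$causal_flag] - qpos)),
              diff(range(rec$pos)) / 4)
  }
})

test_that("swapping bulks negates delta at every site and window", {
  rec <- random_records(200, seed = 3)
  swapped <- rec
  swapped[c("high_ref", "high_alt", "low_ref", "low_alt")] <-
    rec[c("low_ref", "low_alt", "high_ref", "high_alt")]
  rec2 <- compute_snp_indices(swapped)
  expect_equal(rec2$delta, -rec$delta)
  w1 <- sliding_window_means(rec, window_size = 1e6, step = 2e5)
  w2 <- sliding_window_means(rec2, window_size = 1e6, step = 2e5)
  expect_equal(w2$mean_delta, -w1$mean_delta)
})

test_that("sliding-window means match a naive double-loop recomputation", {
  rec <- random_records(200, seed = 19)
  for (params in list(c(1e6, 1e5), c(5e5, 5e4), c(1.2e6, 3e5))) {
    w <- sliding_window_means(rec, window_size = params[1], step = params[2])
    bf <- brute_force_windows(rec, window_size = params[1], step = params[2])
    expect_equal(w$n_snps, bf$n_snps)
    expect_equal(w$mean_delta, bf$mean_delta, tolerance = 1e-12)
    expect_equal(w$mean_index_high, bf$mean_index_high, tolerance = 1e-12)
    expect_equal(w$mean_index_low, bf$mean_index_low, tolerance = 1e-12)
  }
})

test_that("single- and two-SNP windows average as stated", {
  rec <- compute_snp_indices(toy_sites(
    high_ref = c(10L, 5L), high_alt = c(0L, 5L),
    low_ref = c(0L, 5L), low_alt = c(10L, 5L),
    pos = c(100L, 600000L)))
  w <- sliding_window_means(rec, window_size = 1e6, step = 1e6)
  expect_equal(w$n_snps[1], 2L)
  expect_equal(w$mean_delta[1], mean(c(-1, 0)))  # -0.5
  w2 <- sliding_window_means(rec[1, ], window_size = 1e6, step = 1e6)
  expect_equal(w2$mean_delta[1], -1)
})
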