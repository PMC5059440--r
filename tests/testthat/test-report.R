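test_that("summary percentages use half-away-from-zero rounding", {
  expect_equal(round_half_away(0.125, 2), 0.13)   # base round() gives 0.12
  expect_equal(round_half_away(-0.125, 2), -0.13)
  tab <- summary_table(locus_counts = c(A = 1, B = 7))
  expect_equal(tab$pct, c(12.5, 87.5))
  empty <- summary_table(locus_counts = c(A = 0, B = 0))
  expect_equal(nrow(empty), 0)
})

test_that("density tracks match a brute-force per-window recount", {
  # single hit: exactly window/step windows contain it
  tr <- density_track(positions = 500, weights = 2, L = 1000, window = 150,
                      step = 10)
  expect_equal(nrow(tr), 100)
  expect_equal(sum(tr$value > 0), 15)
  expect_equal(sum(tr$value), 15 * 2)

  set.seed(91)
  L <- 173                                      # step does not divide L
  pos <- runif(12, 0, L)
  w <- sample(1:5, 12, replace = TRUE)
  for (circular in c(TRUE, FALSE)) {
    got <- density_track(pos, w, L, window = 30, step = 7,
                         circular = circular)
    expect_equal(nrow(got), ceiling(L / 7))
    naive <- vapply(got$window_start, function(s) {
      inwin <- if (circular) ((pos - s) %% L) < 30 else
        pos >= s & pos < s + 30
      sum(w[inwin])
    }, 0)
    expect_equal(got$value, naive)
  }
  expect_true(all(density_track(numeric(0), numeric(0), 100)$value == 0))
})

test_that("composition deviations are centred and detect forced bases", {
  set.seed(93)
  sp <- vapply(1:200, function(i) paste0("A", random_dna(31)), "")
  dev <- composition_deviation(sp)
  expect_equal(dev[, 1], c(A = 75, C = -25, G = -25, T = -25))
  expect_true(all(abs(colSums(dev)) < 1e-9))

  sp2 <- vapply(1:10000, function(i) random_dna(32), "")
  dev2 <- composition_deviation(sp2)
  se_pp <- 100 * sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(dev2) < 3 * se_pp * 1.5))   # allowance for 128 cells
  # PAM-end indexing reverses the position axis
  dev3 <- composition_deviation(sp, from_pam_end = TRUE)
  expect_equal(dev3[, 32], dev[, 1])
})

test_that("rarefaction saturates exactly and matches the expectation oracle", {
  items <- c("a", "b", "c")
  counts <- c(60, 25, 15)
  full <- rarefaction(items, counts, depths = 100, m = 5)
  expect_equal(full$mean_unique, 3)
  expect_equal(full$sd_unique, 0)
  one <- rarefaction(items, counts, depths = 1, m = 5)
  expect_equal(one$mean_unique, 1)

  set.seed(95)
  d <- 10
  r <- rarefaction(items, counts, depths = d, m = 400)
  # exact hypergeometric expectation of the unique count
  N <- sum(counts)
  e_unique <- sum(1 - choose(N - counts, d) / choose(N, d))
  se <- r$sd_unique / sqrt(400)
  expect_lt(abs(r$mean_unique - e_unique), 3 * se + 1e-9)
})

test_that("hotspot detection finds spike runs over the nonzero median", {
  tr <- data.frame(window_start = seq(0, 990, 10),
                   value = base::rep(1, 100))
  tr$value[41:45] <- 20
  hs <- hotspot_detection(tr, min_fold = 5, min_windows = 3)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$start_window, 400)
  expect_equal(hs$end_window, 440)
  expect_equal(hs$peak_value, 20)

  expect_equal(nrow(hotspot_detection(
    data.frame(window_start = 0:9, value = base::rep(2, 10)),
    min_fold = 2, min_windows = 1)), 0)

  tr2 <- tr
  tr2$value[81:84] <- 30                        # second, separated spike
  hs2 <- hotspot_detection(tr2, min_fold = 5, min_windows = 3)
  expect_equal(nrow(hs2), 2)

  none <- hotspot_detection(data.frame(window_start = 0:9,
                                       value = numeric(10)), 5, 3)
  expect_equal(nrow(none), 0)
})

test_that("clone enrichment flags samples above the strict threshold", {
  mk <- function(shares, sample = "S1") {
    data.frame(sample_id = sample, array_id = paste0("a", seq_along(shares)),
               spacer_seq = paste0("sp", seq_along(shares)),
               read_count = shares, is_new = TRUE, s_index = 1L,
               status = "ok", stringsAsFactors = FALSE)
  }
  qc <- replicate_qc(mk(c(90, 5, 5)))
  expect_true(qc$flagged)
  qc2 <- replicate_qc(mk(base::rep(10, 10)))
  expect_false(qc2$flagged)
  qc3 <- replicate_qc(mk(c(30, 25, 25, 20)))    # top share exactly 30%: strict
  expect_false(qc3$flagged)
})

test_that("pipeline tallies feed the summary table", {
  sh <- shared_sim()
  t <- tally_spacers(sh$pl$annotated)
  tab <- summary_table(t$locus_counts, t$target_counts)
  expect_equal(sum(t$locus_counts), sum(t$target_counts))
  locus <- tab[tab$section == "locus", ]
  expect_lt(abs(sum(locus$pct) - 100), 0.05)
  expect_gt(locus$pct[locus$group == "CRISPR1"], 50)
  expect_gt(t$unique_protospacers, 0)
})
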