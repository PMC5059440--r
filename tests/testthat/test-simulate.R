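# One GG anchor per strand: plant a single GG in a GG-free background.
single_gg_refset <- function(len = 200, at = 120) {
  set.seed(3)
  base <- paste(sample(c("A", "T"), len, replace = TRUE), collapse = "")
  substr(base, at + 1, at + 2) <- "GG"
  reference_set(list(replicon("p1", base, "circular", "plasmid")))
}

test_that("sim_config validates probabilities and weights", {
  expect_error(sim_config(p_len33 = 1.2), "probabilities")
  expect_error(sim_config(naive_rate = 0.6, priming_rate = 0.6), "> 1")
  expect_error(sim_config(slip_dist = c(`1` = 0.99, `-1` = 0.02)), "residual")
  expect_error(sim_config(slip_dist = c(`4` = 0.1)), "offsets")
  cfg <- sim_config(locus_weights = c(A = 2, B = 2))
  expect_equal(unname(cfg$locus_weights), c(0.5, 0.5))
})

test_that("a single GG anchor is sampled with probability 1", {
  rs <- single_gg_refset()
  cfg <- sim_config()
  set.seed(1)
  for (i in 1:5) {
    site <- sample_naive_site(rs, "p1", cfg)
    expect_equal(site$anchor, 120)
    expect_equal(site$strand, "+")   # the complement CC indexes the - strand
  }
})

test_that("naive sampling follows hotspot profiles and the A/T anchor bias", {
  set.seed(21)
  rs <- reference_set(list(replicon("p1", random_dna(2000), "circular",
                                    "plasmid")))
  cfg <- sim_config(p_at_start_bias = 1)
  # background: adjacent-base composition over all GG anchors
  idx <- adaptscan:::gg_anchor_index(rs)
  at_bg <- mean(c(idx$p1[["+"]]$at, idx$p1[["-"]]$at))
  n <- 4000
  draws <- replicate(n, {
    s <- sample_naive_site(rs, "p1", cfg, index = idx)
    key <- paste(s$anchor, s$strand)
  })
  at_of <- c(stats::setNames(idx$p1[["+"]]$at,
                             paste(idx$p1[["+"]]$anchor, "+")),
             stats::setNames(idx$p1[["-"]]$at,
                             paste(idx$p1[["-"]]$anchor, "-")))
  at_frac <- mean(at_of[draws])
  se <- sqrt(at_bg * (1 - at_bg) / n)
  expect_lt(abs(at_frac - at_bg), 3 * se)

  # doubling the profile on an interval doubles its relative draw rate
  w <- base::rep(1, 2000)
  w[501:1000] <- 2
  draws2 <- replicate(n, {
    s <- sample_naive_site(rs, "p1", cfg, weights = w, index = idx)
    s$anchor >= 500 && s$anchor < 1000
  })
  n_in <- sum(vapply(c(idx$p1[["+"]]$anchor, idx$p1[["-"]]$anchor),
                     function(a) a >= 500 && a < 1000, TRUE))
  n_all <- length(at_of)
  p_exp <- 2 * n_in / (n_all + n_in)
  se2 <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(mean(draws2) - p_exp), 3 * se2)
})

test_that("forced quadrants put seeded sites on the displaced strand, 5'", {
  set.seed(31)
  rs <- reference_set(list(replicon("p1", random_dna(3000), "circular",
                                    "plasmid")))
  cfg <- sim_config(quadrant_weights = c(1, 0, 0, 0), translocation_mean = 100)
  seed <- list(replicon_id = "p1", mid = 1500, strand = "-")
  for (i in 1:30) {
    s <- sample_seeded_site(seed, rs, cfg)
    expect_equal(s$strand, "+")
    iv <- adaptscan:::site_interval(s, 0L, 32L, 3000)
    d <- travel_distance(1500, ((iv[["start"]] + iv[["end"]]) / 2) %% 3000,
                         s$strand, 3000, TRUE)
    expect_gt(d, 0)
  }
})

test_that("a vanishing translocation mean selects the nearest eligible GG", {
  set.seed(33)
  rs <- single_gg_refset(len = 400, at = 100)
  # one additional GG, further away in the walk direction
  seq2 <- rs$replicons$p1$seq
  substr(seq2, 301, 302) <- "GG"
  rs2 <- reference_set(list(replicon("p1", seq2, "circular", "plasmid")))
  cfg <- sim_config(quadrant_weights = c(0, 1, 0, 0), translocation_mean = 1,
                    p_at_start_bias = 1)
  # seed on minus strand at 200: displaced-3' walk = increasing coordinates
  seed <- list(replicon_id = "p1", mid = 200, strand = "-")
  s <- sample_seeded_site(seed, rs2, cfg)
  expect_equal(s$strand, "+")
  expect_equal(s$anchor, 300)  # nearest anchor beyond the seed in that arc
})

test_that("default quadrant weights are recovered by Monte Carlo", {
  set.seed(41)
  rs <- reference_set(list(replicon("p1", random_dna(5000), "circular",
                                    "plasmid")))
  cfg <- sim_config()
  seed <- list(replicon_id = "p1", mid = 2500, strand = "-")
  n <- 4000
  q <- replicate(n, sample_seeded_site(seed, rs, cfg)$quadrant)
  frac <- mean(q == 1)
  se <- sqrt(0.625 * 0.375 / n)
  expect_lt(abs(frac - 0.625), 3 * se)
})

test_that("capture errors follow the slip/flip/length semantics", {
  set.seed(51)
  rs <- reference_set(list(replicon("p1", random_dna(2000), "circular",
                                    "plasmid")))
  cfg0 <- sim_config(slip_dist = c(`1` = 0), p_flip_given_small_slip = 0,
                     p_flip_given_big_slip = 0)
  idx <- adaptscan:::gg_anchor_index(rs)
  rpl <- rs$replicons$p1
  for (i in 1:20) {
    site <- sample_naive_site(rs, "p1", cfg0, index = idx)
    ev <- apply_capture_errors(site, rs, cfg0)$event
    expect_true(nchar(ev$spacer_seq) %in% c(32, 33))
    ctx <- adaptscan:::site_context(rpl, ev$start, ev$end, ev$strand)
    expect_equal(substr(ctx$flank3, 1, 2), "GG")   # error-free limit
    # slip -1 incorporates a G at the spacer 3' end
    ev1 <- apply_capture_errors(site, rs, cfg0, slip = -1L, flipped = FALSE,
                                len = 33L)$event
    expect_equal(substr(ev1$spacer_seq, 33, 33), "G")
    # a flipped slip-0 capture leaves CC immediately 5' of its mapped hit
    evf <- apply_capture_errors(site, rs, cfg0, slip = 0L, flipped = TRUE,
                                len = 32L)$event
    hit <- map_spacer(evf$spacer_seq, rs)
    expect_equal(nrow(hit), 1)
    expect_equal(hit$strand, setdiff(c("+", "-"), ev$strand))
    expect_true(endsWith(hit$flank5, "CC"))
    expect_true(call_flip(hit$flank5, hit$spacer_seq))
  }
})

test_that("population simulation honours degenerate configurations", {
  rs <- synthetic_references(seed = 42)$refset
  cfg0 <- sim_config(n_cells = 50, naive_rate = 0, priming_rate = 0,
                     chrom_event_rate = 0, seed = 5)
  expect_equal(nrow(simulate_population(rs, cfg0)$events), 0)

  cfg1 <- sim_config(n_cells = 40, naive_rate = 0, priming_rate = 1,
                     feedback_mean = 0, chrom_event_rate = 0, seed = 6)
  tr <- simulate_population(rs, cfg1)$events
  expect_equal(nrow(tr), 40)
  expect_true(all(tr$k == 1))
  expect_true(all(tr$mechanism == "primed"))
})

test_that("identical seeds give byte-identical simulations and reads", {
  sr <- synthetic_references(seed = 42)
  cfg <- sim_config(n_cells = 60, seed = 9)
  t1 <- simulate_population(sr$refset, cfg)
  t2 <- simulate_population(sr$refset, cfg)
  expect_identical(t1$events, t2$events)
  e1 <- emit_amplicons(t1, sr$refset, sr$barcode_table, "S1", cfg)
  e2 <- emit_amplicons(t2, sr$refset, sr$barcode_table, "S1", cfg)
  expect_identical(e1$reads, e2$reads)
})

test_that("canonical-PAM chromosomal events are terminal within their cell", {
  sr <- synthetic_references(seed = 42)
  cfg <- sim_config(n_cells = 150, chrom_event_rate = 1, seed = 13)
  tr <- simulate_population(sr$refset, cfg)$events
  chrom <- tr[tr$mechanism == "chromosomal" & tr$slip == 0 & !tr$flipped, ]
  last_k <- tapply(tr$k, tr$cell_id, max)
  expect_true(all(chrom$k == last_k[as.character(chrom$cell_id)]))
})

test_that("amplicons carry the newest spacer leader-proximal and round-trip", {
  sr <- synthetic_references(seed = 42)
  cfg <- sim_config(n_cells = 1, seed = 2)
  locus <- sr$refset$loci$CRISPR1
  truth <- structure(list(events = data.frame(
    cell_id = 1L, k = 1:2, locus_id = "CRISPR1", replicon_id = "pSim",
    start = c(100L, 300L), end = c(132L, 332L), strand = "+",
    mechanism = c("primed", "targeted"), slip = 0L, flipped = FALSE,
    spacer_seq = c(fetch(sr$refset$replicons$pSim, 100, 132, "+"),
                   fetch(sr$refset$replicons$pSim, 300, 332, "+")),
    stringsAsFactors = FALSE), config = cfg), class = "AcquisitionTruth")
  em <- emit_amplicons(truth, sr$refset, sr$barcode_table, "S1", cfg)
  expect_length(em$reads, 1)
  ex <- extract_array(unname(em$reads[1]), locus$repeat_seq)
  expect_equal(ex$status, "ok")
  expect_equal(ex$spacers,
               c(truth$events$spacer_seq[2], truth$events$spacer_seq[1],
                 locus$preexisting_spacers[1]))
  # read count equals (cell, locus) pairs with >= 1 event
  expect_equal(length(em$reads),
               nrow(unique(truth$events[, c("cell_id", "locus_id")])))
})
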