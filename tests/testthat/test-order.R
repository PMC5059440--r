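test_that("travel distances follow the shortest-arc 5'-positive convention", {
  # circular L=1000: from mid 500, to mid 400 on + is 5' (decreasing) => +100
  expect_equal(travel_distance(500, 400, "+", 1000), 100)
  expect_equal(travel_distance(500, 400, "-", 1000), -100)
  expect_equal(travel_distance(500, 500, "+", 1000), 0)
  # wrap: 950 -> 50 is +100 in plus coordinates => 3' on +, 5' on -
  expect_equal(travel_distance(950, 50, "+", 1000), -100)
  expect_equal(travel_distance(950, 50, "-", 1000), 100)
  # antipodal ties are undefined
  expect_true(is.na(travel_distance(0, 500, "+", 1000)))
  # linear: no wrap
  expect_equal(travel_distance(10, 990, "+", 1000, circular = FALSE), -980)
})

test_that("travel distance is antisymmetric on same-strand pairs", {
  set.seed(81)
  for (i in 1:50) {
    L <- sample(50:2000, 1)
    a <- runif(1, 0, L); b <- runif(1, 0, L)
    s <- sample(c("+", "-"), 1)
    d1 <- travel_distance(a, b, s, L)
    d2 <- travel_distance(b, a, s, L)
    if (!is.na(d1)) expect_equal(d1, -d2)
  }
})

test_that("shortest-arc distances are bounded by half the replicon", {
  L <- 10
  for (a in 0:9) for (b in 0:9) for (s in c("+", "-")) {
    d <- travel_distance(a, b, s, L)
    arcs <- c((b - a) %% L, (a - b) %% L)
    if (min(arcs) == L / 2) {
      expect_true(is.na(d))
    } else {
      expect_equal(abs(d), min(arcs))
      expect_true(abs(d) <= L / 2)
    }
  }
})

make_annotated <- function(mapped_y = TRUE) {
  data.frame(array_id = "a1", sample_id = "S1", locus_id = "CRISPR1",
             read_count = 3L, position = 1:3,
             spacer_seq = c("xxx", "yyy", "pre"), is_new = c(TRUE, TRUE, FALSE),
             s_index = c(2L, 1L, NA), anomalous = FALSE, status = "ok",
             target_class = c("plasmid", "plasmid", "plasmid"),
             multi_locus = FALSE,
             replicon_id = "p",
             start = c(100L, if (mapped_y) 300L else NA, 1L),
             end = c(132L, if (mapped_y) 332L else NA, 33L),
             strand = "+", flank5 = "AAAAA", flank3 = "GGAAA", pam = "GG",
             rescued = FALSE, pam_category = "GG", slip_offset = 0L,
             slip_other = FALSE, flip_candidate = FALSE,
             stringsAsFactors = FALSE)
}

test_that("order joins PS+k to mapping and tolerates unmapped intermediates", {
  oh <- order_hits(make_annotated())
  expect_equal(nrow(oh), 2)
  expect_equal(oh$k[oh$mid == (300 + 332) / 2], 1)   # PS+1 = map of S+1 (yyy)
  expect_equal(oh$k[oh$mid == (100 + 132) / 2], 2)

  oh2 <- order_hits(make_annotated(mapped_y = FALSE))
  expect_equal(sort(oh2$k), c(1, 2))
  expect_false(oh2$mapped[oh2$k == 1])               # PS+1 absent
  expect_true(oh2$mapped[oh2$k == 2])                # PS+2 keeps its k
})

test_that("forced displaced-5' simulations land all PS+1 mass in one cell", {
  sr <- synthetic_references(seed = 42)
  cfg <- sim_config(n_cells = 150, quadrant_weights = c(1, 0, 0, 0),
                    naive_rate = 0, priming_rate = 1, chrom_event_rate = 0,
                    feedback_mean = 0, seed = 17)
  truth <- simulate_population(sr$refset, cfg)
  em <- emit_amplicons(truth, sr$refset, sr$barcode_table, "S1", cfg)
  pl <- run_pipeline(em$reads, sr$refset, sr$barcode_table)
  pps <- sr$refset$seed_sites[1, ]
  s1 <- pl$ordered[pl$ordered$k == 1 & pl$ordered$mapped, ]
  m <- five_three_split(s1, pps, sr$refset)
  expect_equal(sum(m), 1)
  expect_equal(m["displaced", "5prime"], 1)
  sf <- strand_fraction_by_order(pl$ordered, pps)
  expect_equal(sf$frac_primed_strand[sf$k == 1], 0)
})

test_that("strand preference alternates with acquisition order", {
  sh <- shared_sim()
  pps <- sh$refs$refset$seed_sites[1, ]
  sf <- strand_fraction_by_order(sh$pl$ordered, pps)
  expect_lt(sf$frac_primed_strand[sf$k == 1], 0.5)   # PS+1: displaced strand
  expect_gt(sf$frac_primed_strand[sf$k == 2], 0.5)   # PS+2: primed strand
  # fractions are proportions of a two-way split
  expect_true(all(sf$frac_primed_strand >= 0 & sf$frac_primed_strand <= 1))
})

test_that("heatmaps conserve weight, transpose under axis swap and show 5' hops", {
  sr <- synthetic_references(seed = 42)
  cfg <- sim_config(n_cells = 250, quadrant_weights = c(1, 0, 0, 0),
                    locus_weights = c(CRISPR1 = 1),
                    p_flip_given_small_slip = 0, p_flip_given_big_slip = 0,
                    translocation_mean = 60, naive_rate = 0, priming_rate = 1,
                    chrom_event_rate = 0, feedback_mean = 3, seed = 19)
  truth <- simulate_population(sr$refset, cfg)
  em <- emit_amplicons(truth, sr$refset, sr$barcode_table, "S1", cfg)
  pl <- run_pipeline(em$reads, sr$refset, sr$barcode_table)
  pps <- sr$refset$seed_sites[1, ]
  spec <- list(c("PPS", "PS1"), c("PS1", "PS2"))
  hm <- travel_heatmap(pl$ordered, pps, sr$refset, spec)
  d1 <- pair_distances(pl$ordered, pps, sr$refset, "PPS", "PS1")
  d2 <- pair_distances(pl$ordered, pps, sr$refset, "PS1", "PS2")
  both <- intersect(d1$array_id, d2$array_id)
  expect_equal(hm$total, sum(d1$weight[d1$array_id %in% both]))

  hm_sw <- travel_heatmap(pl$ordered, pps, sr$refset, rev(spec))
  expect_equal(hm_sw$counts, t(hm$counts))

  # every hop is forced 5': mass concentrates in the (+,+) quadrant (captures
  # within a couple of nt of the seed can drift marginally 3' once slips and
  # aberrant lengths shift the midpoint)
  pos <- hm$x_breaks[-1] > 0
  expect_gt(sum(hm$counts[pos, pos]) / hm$total, 0.95)
})

test_that("chromosomal spacers sit leader-proximal unless their PAM escaped", {
  sr <- synthetic_references(seed = 42)
  cfg <- sim_config(n_cells = 250, chrom_event_rate = 1,
                    slip_dist = c(`1` = 0), p_flip_given_small_slip = 0,
                    p_flip_given_big_slip = 0, seed = 23)
  truth <- simulate_population(sr$refset, cfg)
  em <- emit_amplicons(truth, sr$refset, sr$barcode_table, "S1", cfg)
  pl <- run_pipeline(em$reads, sr$refset, sr$barcode_table)
  st <- terminal_position_stat(pl$annotated)
  expect_equal(st$fraction_terminal, 1)

  cfg2 <- sim_config(n_cells = 400, chrom_event_rate = 1,
                     slip_dist = c(`-1` = 0.25, `1` = 0.25), seed = 27)
  truth2 <- simulate_population(sr$refset, cfg2)
  em2 <- emit_amplicons(truth2, sr$refset, sr$barcode_table, "S1", cfg2)
  pl2 <- run_pipeline(em2$reads, sr$refset, sr$barcode_table)
  st2 <- terminal_position_stat(pl2$annotated)
  expect_lt(st2$fraction_terminal, 1)

  # no chromosomal spacers: undefined result
  st0 <- terminal_position_stat(make_annotated())
  expect_true(is.na(st0$fraction_terminal))
})
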