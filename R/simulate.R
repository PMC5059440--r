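#' Simulation configuration
#'
#' Parameters of the generative adaptation model: cells acquire spacers
#' through naive capture (anywhere on the plasmid, PAM-anchored), primed
#' capture (seeded by the priming protospacer, PPS) or targeted capture
#' (seeded by the immediately preceding interference-proficient acquisition,
#' forming the positive feedback loop). Capture errors -- PAM slipping and
#' spacer flipping -- are drawn per event.
#'
#' Defaults follow the statistics of the modelled type I-F system: ~92%
#' canonical GG captures with slips up to +/-3 nt; 32 nt spacers ~90% and
#' 33 nt ~10%; locus shares ~70/28/2% across CRISPR1-3; ~62.5% of initial
#' primed captures 5' of the PPS on the displaced strand; priming >= 500x
#' more active than naive acquisition.
#'
#' @param n_cells number of cells to simulate.
#' @param locus_weights named per-locus integration shares (normalised).
#' @param p_len33 probability of a 33 nt capture (canonical/plus slips).
#' @param p_len_other probability of another aberrant length (30,31,34,35).
#' @param slip_dist named numeric over offsets `-3..-1, 1..3`; the residual
#'   mass is the canonical (slip 0) probability.
#' @param p_flip_given_small_slip flip probability when |slip| <= 1.
#' @param p_flip_given_big_slip flip probability when |slip| >= 2.
#' @param naive_rate per-cell probability of starting a naive chain.
#' @param priming_rate per-cell probability of starting a primed chain.
#' @param quadrant_weights length-4 weights for the seeded-capture quadrant
#'   (displaced-5', displaced-3', target-5', target-3') relative to the
#'   current seed; "displaced" is the strand opposite the seed protospacer,
#'   and 5'/3' is evaluated on the strand of the new protospacer.
#' @param translocation_mean mean of the geometric translocation kernel (nt)
#'   governing how far the machinery walks along successive GG sites.
#' @param feedback_mean mean of the truncated-geometric number of additional
#'   targeted events per chain.
#' @param feedback_cap upper truncation of the feedback extension.
#' @param chrom_event_rate per-cell probability of a chromosomal capture.
#' @param p_at_start_bias multiplier favouring GG anchors whose PAM-proximal
#'   protospacer base is A/T (1 = off).
#' @param read_error_rate per-base substitution rate applied to emitted reads.
#' @param seed RNG seed used by [simulate_population()].
#' @return an object of class `SimConfig` (a validated list).
#' @export
sim_config <- function(n_cells = 1000,
                       locus_weights = c(CRISPR1 = 0.70, CRISPR2 = 0.28,
                                         CRISPR3 = 0.02),
                       p_len33 = 0.10,
                       p_len_other = 0.005,
                       slip_dist = c(`-3` = 0.003, `-2` = 0.007, `-1` = 0.03,
                                     `1` = 0.03, `2` = 0.007, `3` = 0.003),
                       p_flip_given_small_slip = 0.002,
                       p_flip_given_big_slip = 0.05,
                       naive_rate = 0.001,
                       priming_rate = 0.5,
                       quadrant_weights = c(displaced_5p = 0.625,
                                            displaced_3p = 0.10,
                                            target_5p = 0.15,
                                            target_3p = 0.125),
                       translocation_mean = 150,
                       feedback_mean = 1.5,
                       feedback_cap = 8,
                       chrom_event_rate = 0.001,
                       p_at_start_bias = 2,
                       read_error_rate = 0,
                       seed = 1L) {
  probs <- c(p_len33, p_len_other, p_flip_given_small_slip,
             p_flip_given_big_slip, naive_rate, priming_rate,
             chrom_event_rate, read_error_rate, slip_dist)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (naive_rate + priming_rate > 1) stop("naive_rate + priming_rate > 1")
  if (sum(slip_dist) >= 1) stop("slip_dist mass must leave residual canonical mass")
  need <- c("-3", "-2", "-1", "1", "2", "3")
  if (!all(names(slip_dist) %in% need)) stop("slip_dist offsets must be in -3..3, excluding 0")
  sd_full <- stats::setNames(numeric(6), need)
  sd_full[names(slip_dist)] <- slip_dist
  if (any(quadrant_weights < 0) || sum(quadrant_weights) <= 0) {
    stop("quadrant_weights must be non-negative with positive sum")
  }
  if (any(locus_weights < 0) || sum(locus_weights) <= 0) {
    stop("locus_weights must be non-negative with positive sum")
  }
  structure(list(
    n_cells = as.integer(n_cells),
    locus_weights = locus_weights / sum(locus_weights),
    p_len33 = p_len33, p_len_other = p_len_other,
    slip_dist = sd_full,
    p_flip_given_small_slip = p_flip_given_small_slip,
    p_flip_given_big_slip = p_flip_given_big_slip,
    naive_rate = naive_rate, priming_rate = priming_rate,
    quadrant_weights = quadrant_weights / sum(quadrant_weights),
    translocation_mean = translocation_mean,
    feedback_mean = feedback_mean, feedback_cap = as.integer(feedback_cap),
    chrom_event_rate = chrom_event_rate,
    p_at_start_bias = p_at_start_bias,
    read_error_rate = read_error_rate,
    seed = as.integer(seed)
  ), class = "SimConfig")
}

# ---- GG anchor index ---------------------------------------------------

# Precompute, per replicon and strand, all GG anchors with the plus-strand
# coordinate of the GG dinucleotide, the approximate canonical protospacer
# midpoint (len 32) used for walk ordering, and the A/T flag of the
# PAM-proximal protospacer base.
gg_anchor_index <- function(refset) {
  idx <- list()
  for (rpl in refset$replicons) {
    L <- rpl$length
    per_strand <- list()
    for (strand in c("+", "-")) {
      g <- scan_motif_sites(rpl, "GG", strand)
      if (strand == "+") {
        adj <- (g - 1L) %% L         # plus base immediately 5' of GG
        mid <- (g - 16) %% L
      } else {
        adj <- (g + 2L) %% L         # complement base; A/T set is closed
        mid <- (g + 2L + 16) %% L
      }
      base <- if (length(adj)) substring(rpl$seq, adj + 1L, adj + 1L) else
        character(0)
      # for linear replicons mask anchors whose protospacer would run off
      keep <- rep(TRUE, length(g))
      if (rpl$topology == "linear") {
        keep <- if (strand == "+") g >= 40 else (g + 2L + 40) <= L
        base[(strand == "+" & g == 0L)] <- "N"
      }
      per_strand[[strand]] <- list(anchor = g[keep], mid = mid[keep],
                                   at = base[keep] %in% c("A", "T"))
    }
    idx[[rpl$id]] <- per_strand
  }
  idx
}

# ---- site sampling -----------------------------------------------------

#' Sample a naive capture site
#'
#' Draws a GG-anchored protospacer site uniformly over all GG anchors of a
#' replicon (both strands), optionally reweighted by a per-position hotspot
#' profile and by the A/T bias on the PAM-proximal base.
#'
#' @param refset a [reference_set()].
#' @param replicon_id replicon to draw from.
#' @param config a [sim_config()].
#' @param weights optional numeric hotspot profile of length L (plus-strand
#'   positions); the weight applied to an anchor is the profile value at the
#'   GG start coordinate. `NULL` means uniform.
#' @param index internal anchor cache (from `gg_anchor_index`); computed if
#'   missing.
#' @return a site: list with `replicon_id`, `anchor` (0-based GG start in
#'   plus coordinates), `strand`.
#' @export
sample_naive_site <- function(refset, replicon_id, config, weights = NULL,
                              index = NULL) {
  if (is.null(index)) index <- gg_anchor_index(refset)
  both <- index[[replicon_id]]
  n_plus <- length(both[["+"]]$anchor)
  anchors <- c(both[["+"]]$anchor, both[["-"]]$anchor)
  if (length(anchors) == 0L) stop("no GG sites on replicon '", replicon_id, "'")
  at <- c(both[["+"]]$at, both[["-"]]$at)
  w <- ifelse(at, config$p_at_start_bias, 1)
  if (!is.null(weights)) {
    w <- w * weights[anchors + 1L]
  }
  i <- sample.int(length(anchors), 1L, prob = w)
  list(replicon_id = replicon_id, anchor = anchors[[i]],
       strand = if (i <= n_plus) "+" else "-")
}

#' Sample a seeded (primed/targeted) capture site
#'
#' Chooses one of four quadrants relative to the seed protospacer by the
#' configured quadrant weights, then walks successive GG anchors away from
#' the seed in that direction, capturing at each encountered anchor with a
#' Bernoulli probability tuned so the mean travel is about
#' `translocation_mean` nt (a geometric hop kernel) and reweighted by the
#' A/T bias on the anchor's PAM-proximal base. On circular replicons
#' directions follow the shortest arc and the walk is confined to the
#' half-arc; on linear replicons a walk that runs off the end resamples the
#' quadrant.
#'
#' @param seed list with `replicon_id`, `mid` (anchor midpoint, plus
#'   coordinates) and `strand` of the seed protospacer.
#' @param refset a [reference_set()].
#' @param config a [sim_config()].
#' @param index internal anchor cache; computed if missing.
#' @return a site (as in [sample_naive_site()]) with an extra element
#'   `quadrant` in 1..4 (displaced-5', displaced-3', target-5', target-3').
#' @export
sample_seeded_site <- function(seed, refset, config, index = NULL) {
  if (is.null(index)) index <- gg_anchor_index(refset)
  rep <- refset$replicons[[seed$replicon_id]]
  L <- rep$length
  circular <- rep$topology == "circular"
  half <- L / 2
  for (try_q in 1:100) {
    q <- sample.int(4L, 1L, prob = config$quadrant_weights)
    new_strand <- if (q <= 2L) flip_strand(seed$strand) else seed$strand
    side5 <- q %in% c(1L, 3L)
    # 5' on plus = decreasing coordinate; 5' on minus = increasing
    decreasing <- (new_strand == "+") == side5
    cand <- index[[seed$replicon_id]][[new_strand]]
    if (length(cand$anchor) == 0L) next
    d <- if (decreasing) (seed$mid - cand$mid) %% L else (cand$mid - seed$mid) %% L
    ok <- d >= 0.5 & (if (circular) d <= half - 2 else d <= L)
    if (!circular) {
      ok <- ok & (if (decreasing) cand$mid < seed$mid else cand$mid > seed$mid)
    }
    if (!any(ok)) next
    ord <- order(d)
    ord <- ord[ok[ord]]
    # Bernoulli capture at each successive GG site: the per-site capture
    # probability is tuned so the mean travel is ~translocation_mean nt,
    # and reweighted by the A/T bias on the site's PAM-proximal base
    w_site <- ifelse(cand$at[ord], config$p_at_start_bias, 1)
    gap_mean <- L / max(1L, length(cand$anchor))
    q0 <- min(1, gap_mean / max(config$translocation_mean, 1e-9))
    p_cap <- pmin(1, q0 * w_site / mean(w_site))
    for (try_w in 1:50) {
      j <- which(stats::runif(length(p_cap)) < p_cap)[1L]
      if (!is.na(j)) {
        return(list(replicon_id = seed$replicon_id,
                    anchor = cand$anchor[[ord[j]]],
                    strand = new_strand, quadrant = q))
      }
    }
    # translocation never landed: fall back to the nearest eligible anchor
    return(list(replicon_id = seed$replicon_id, anchor = cand$anchor[[ord[1L]]],
                strand = new_strand, quadrant = q))
  }
  stop("sample_seeded_site: no eligible GG anchors near seed")
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# ---- capture errors ----------------------------------------------------

draw_slip <- function(config) {
  p <- config$slip_dist
  u <- stats::runif(1L)
  if (u >= sum(p)) return(0L)
  as.integer(names(p)[findInterval(u, cumsum(p), left.open = TRUE) + 1L])
}

draw_length <- function(config, slip) {
  if (slip < 0L) return(sample(33:36, 1L))
  u <- stats::runif(1L)
  if (u < config$p_len33) 33L
  else if (u < config$p_len33 + config$p_len_other) sample(c(30L, 31L, 34L, 35L), 1L)
  else 32L
}

# Protospacer interval (plus coordinates, end may exceed L on circular
# replicons) for a GG anchor, slip offset and length. The slip shifts the
# 3' boundary: slip s puts the protospacer 3' end at (GG start - s) in
# strand-local terms, so -1 incorporates the first G of the PAM.
site_interval <- function(site, slip, len, L) {
  if (site$strand == "+") {
    start <- (site$anchor - slip - len) %% L
  } else {
    start <- (site$anchor + 2L + slip) %% L
  }
  c(start = start, end = start + len)
}

# Sequence context of a protospacer interval on its strand: 5' flank (5 nt),
# the protospacer itself, and 3' flank (5 nt); out-of-bounds flanks on
# linear replicons are N-padded.
site_context <- function(rep, start, end, strand) {
  len <- end - start
  if (strand == "+") {
    list(spacer = fetch_padded(rep, start, end, "+"),
         flank5 = fetch_padded(rep, start - 5L, start, "+"),
         flank3 = fetch_padded(rep, end, end + 5L, "+"))
  } else {
    list(spacer = fetch_padded(rep, start, end, "-"),
         flank5 = fetch_padded(rep, end, end + 5L, "-"),
         flank3 = fetch_padded(rep, start - 5L, start, "-"))
  }
}

#' Apply capture errors to a sampled site
#'
#' Draws a slip offset, flip decision and spacer length, constructs the
#' resulting acquisition event and reports whether the windowed-GG
#' classifier applied to the event's own sequence context identifies the
#' drawn slip (i.e. whether the event is identifiable; see the methods
#' vignette on re-anchoring in G-dense contexts).
#'
#' @param site a site from [sample_naive_site()]/[sample_seeded_site()].
#' @param refset a [reference_set()].
#' @param config a [sim_config()].
#' @param slip,flipped,len optionally pre-drawn error values (used by the
#'   population simulator to hold errors fixed while resampling sites).
#' @return list with `event` (a one-row data.frame) and `consistent` (flag).
#' @export
apply_capture_errors <- function(site, refset, config,
                                 slip = NULL, flipped = NULL, len = NULL) {
  rep <- refset$replicons[[site$replicon_id]]
  if (is.null(slip)) slip <- draw_slip(config)
  if (is.null(flipped)) {
    p_flip <- if (abs(slip) >= 2L) config$p_flip_given_big_slip else
      config$p_flip_given_small_slip
    flipped <- stats::runif(1L) < p_flip
  }
  if (is.null(len)) len <- draw_length(config, slip)
  iv <- site_interval(site, slip, len, rep$length)
  ctx <- site_context(rep, iv[["start"]], iv[["end"]], site$strand)
  call <- call_slip(ctx$spacer, ctx$flank3)
  consistent <- !grepl("N", paste0(ctx$flank5, ctx$spacer, ctx$flank3)) &&
    !call$other && !is.na(call$slip_offset) && call$slip_offset == slip
  spacer_seq <- if (flipped) rev_comp(ctx$spacer) else ctx$spacer
  event <- data.frame(replicon_id = site$replicon_id,
                      start = iv[["start"]], end = iv[["end"]],
                      strand = site$strand, slip = slip, flipped = flipped,
                      spacer_seq = spacer_seq, stringsAsFactors = FALSE)
  list(event = event, consistent = consistent)
}

# Draw errors once, then resample the site until the drawn slip is
# identifiable from the resulting context (re-anchoring assumption).
capture_with_retries <- function(sampler, refset, config, max_tries = 30L) {
  slip <- draw_slip(config)
  p_flip <- if (abs(slip) >= 2L) config$p_flip_given_big_slip else
    config$p_flip_given_small_slip
  flipped <- stats::runif(1L) < p_flip
  len <- draw_length(config, slip)
  res <- NULL
  for (i in seq_len(max_tries)) {
    site <- sampler()
    res <- apply_capture_errors(site, refset, config, slip, flipped, len)
    res$site <- site
    if (res$consistent) return(res)
  }
  res
}

# ---- population simulation --------------------------------------------

#' Simulate a population of adapting cells
#'
#' Per cell: with `naive_rate` a naive chain starts anywhere on the plasmid;
#' with `priming_rate` a primed chain starts at the configured seed site
#' (PPS). Every subsequent event in a chain is seeded by the most recent
#' interference-proficient event (canonical PAM, not flipped) -- the
#' targeted-acquisition feedback loop. The chain length beyond the first
#' event is truncated-geometric with mean `feedback_mean`. Rare chromosomal
#' captures occur with `chrom_event_rate` and are terminal when their PAM is
#' canonical. Each event integrates into a locus drawn by `locus_weights`.
#'
#' @param refset a [reference_set()] with at least one plasmid carrying a
#'   seed site (when `priming_rate > 0`) and one chromosome (when
#'   `chrom_event_rate > 0`). A seed site placed on the chromosome models
#'   self-priming (e.g. a plasmid-derived spacer with partial chromosomal
#'   similarity): chromosomal captures are then seeded at it instead of
#'   being drawn naively.
#' @param config a [sim_config()].
#' @param chrom_profile optional per-position hotspot profile for naive
#'   chromosomal captures (see [sample_naive_site()]); uniform when NULL.
#' @return an `AcquisitionTruth` list: `events` (data.frame with `cell_id`,
#'   `k`, `locus_id`, `replicon_id`, `start`, `end`, `strand`, `mechanism`,
#'   `slip`, `flipped`, `spacer_seq`), plus the `config` echo.
#' @export
simulate_population <- function(refset, config, chrom_profile = NULL) {
  set.seed(config$seed)
  index <- gg_anchor_index(refset)
  roles <- vapply(refset$replicons, `[[`, "", "role")
  plasmid_id <- names(roles)[roles == "plasmid"][1]
  chrom_id <- names(roles)[roles == "chromosome"][1]
  seed0 <- chrom_seed <- NULL
  if (!is.null(refset$seed_sites) && nrow(refset$seed_sites)) {
    as_seed <- function(s) list(replicon_id = s$replicon_id,
                                mid = ((s$start + s$end) / 2) %%
                                  refset$replicons[[s$replicon_id]]$length,
                                strand = s$strand, kind = s$kind)
    on_chrom <- roles[refset$seed_sites$replicon_id] == "chromosome"
    if (any(!on_chrom)) seed0 <- as_seed(refset$seed_sites[which(!on_chrom)[1], ])
    if (any(on_chrom)) chrom_seed <- as_seed(refset$seed_sites[which(on_chrom)[1], ])
  }
  loci <- names(config$locus_weights)

  out <- vector("list", config$n_cells)
  for (cell in seq_len(config$n_cells)) {
    u <- stats::runif(1L)
    mech0 <- if (u < config$naive_rate) "naive"
      else if (u < config$naive_rate + config$priming_rate) {
        if (!is.null(seed0) && identical(seed0$kind, "targeted")) "targeted" else "primed"
      } else NA_character_
    events <- list()
    cur_seed <- NULL
    if (!is.na(mech0)) {
      if (mech0 != "naive" && is.null(seed0)) {
        stop("priming_rate > 0 but the reference set has no seed site")
      }
      n_events <- 1L + min(stats::rgeom(1L, 1 / (1 + config$feedback_mean)),
                           config$feedback_cap)
      for (j in seq_len(n_events)) {
        sampler <- if (j == 1L && mech0 == "naive") {
          function() sample_naive_site(refset, plasmid_id, config, index = index)
        } else {
          sd <- if (j == 1L) seed0 else cur_seed %||% seed0
          local({
            sd_ <- sd
            function() sample_seeded_site(sd_, refset, config, index = index)
          })
        }
        res <- capture_with_retries(sampler, refset, config)
        ev <- res$event
        ev$mechanism <- if (j == 1L) mech0 else "targeted"
        events[[length(events) + 1L]] <- ev
        if (ev$slip == 0L && !ev$flipped) {
          cur_seed <- list(replicon_id = ev$replicon_id,
                           mid = ((ev$start + ev$end) / 2) %%
                             refset$replicons[[ev$replicon_id]]$length,
                           strand = ev$strand)
        }
      }
    }
    if (!is.na(chrom_id) && stats::runif(1L) < config$chrom_event_rate) {
      # with a chromosomal self-priming seed present, most chromosomal
      # captures are driven by it; the rest stay naive (dispersed)
      seeded_chrom <- !is.null(chrom_seed) && stats::runif(1L) < 0.7
      chrom_sampler <- if (seeded_chrom) {
        function() sample_seeded_site(chrom_seed, refset, config, index = index)
      } else {
        function() sample_naive_site(refset, chrom_id, config,
                                     weights = chrom_profile, index = index)
      }
      res <- capture_with_retries(chrom_sampler, refset, config)
      ev <- res$event
      ev$mechanism <- "chromosomal"
      events[[length(events) + 1L]] <- ev
      if ((ev$slip != 0L || ev$flipped) && !is.null(cur_seed) &&
          stats::runif(1L) < 0.5) {
        # non-canonical chromosomal PAM escapes interference: the plasmid
        # feedback loop may continue past it
        res2 <- capture_with_retries(
          function() sample_seeded_site(cur_seed, refset, config, index = index),
          refset, config)
        ev2 <- res2$event
        ev2$mechanism <- "targeted"
        events[[length(events) + 1L]] <- ev2
      }
    }
    if (length(events)) {
      df <- do.call(rbind, events)
      df$cell_id <- cell
      df$k <- seq_len(nrow(df))
      df$locus_id <- sample(loci, nrow(df), replace = TRUE,
                            prob = config$locus_weights)
      out[[cell]] <- df
    }
  }
  events <- if (all(vapply(out, is.null, TRUE))) {
    data.frame(replicon_id = character(0), start = integer(0),
               end = integer(0), strand = character(0), slip = integer(0),
               flipped = logical(0), spacer_seq = character(0),
               mechanism = character(0), cell_id = integer(0),
               k = integer(0), locus_id = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out[!vapply(out, is.null, TRUE)])
  }
  rownames(events) <- NULL
  cols <- c("cell_id", "k", "locus_id", "replicon_id", "start", "end",
            "strand", "mechanism", "slip", "flipped", "spacer_seq")
  structure(list(events = events[, cols], config = config),
            class = "AcquisitionTruth")
}

#' @export
print.AcquisitionTruth <- function(x, ...) {
  cat(sprintf("AcquisitionTruth: %d events in %d cells\n",
              nrow(x$events), length(unique(x$events$cell_id))))
  if (nrow(x$events)) print(table(x$events$mechanism))
  invisible(x)
}

# ---- amplicon emission -------------------------------------------------

#' Emit amplicon reads from a simulated population
#'
#' One read per (cell, locus) with at least one new spacer: the 5' barcode,
#' the leader tail, then repeat+spacer units with the last-acquired spacer
#' leader-proximal, then repeat + pre-existing spacer 1 + repeat +
#' pre-existing spacer 2 (which doubles as the 3' primer tag). Optional
#' uniform per-base substitution noise.
#'
#' @param truth an `AcquisitionTruth` from [simulate_population()].
#' @param refset a [reference_set()] whose loci define repeat, leader tail
#'   and pre-existing spacers.
#' @param barcode_table data.frame with `sample_id`, `locus_id`, `barcode5`,
#'   `tag3`.
#' @param sample_id sample to emit (must appear in `barcode_table`).
#' @param config a [sim_config()] (for `read_error_rate`).
#' @return list with `reads` (named character vector; names are read ids),
#'   `read_map` (data.frame `read_id`, `sample_id`, `locus_id`, `cell_id`)
#'   and `truth` (the event log, unchanged).
#' @export
emit_amplicons <- function(truth, refset, barcode_table, sample_id, config) {
  ev <- truth$events
  bt <- barcode_table[barcode_table$sample_id == sample_id, ]
  reads <- character(0)
  map <- list()
  if (nrow(ev)) {
    ev <- ev[order(ev$cell_id, ev$k), ]
    key <- paste(ev$cell_id, ev$locus_id)
    for (grp in split(seq_len(nrow(ev)), key)) {
      cell <- ev$cell_id[grp[1L]]
      locus_id <- ev$locus_id[grp[1L]]
      locus <- refset$loci[[locus_id]]
      b <- bt[bt$locus_id == locus_id, ]
      if (nrow(b) == 0L) next
      spacers <- rev(ev$spacer_seq[grp])          # newest leader-proximal
      body <- paste0(locus$repeat_seq, c(spacers, locus$preexisting_spacers),
                     collapse = "")
      read <- paste0(b$barcode5, locus$leader_tail, body)
      if (config$read_error_rate > 0) {
        read <- mutate_read(read, config$read_error_rate)
      }
      rid <- sprintf("%s_%s_c%06d", sample_id, locus_id, cell)
      reads[rid] <- read
      map[[length(map) + 1L]] <- data.frame(read_id = rid,
                                            sample_id = sample_id,
                                            locus_id = locus_id,
                                            cell_id = cell,
                                            stringsAsFactors = FALSE)
    }
  }
  read_map <- if (length(map)) do.call(rbind, map) else
    data.frame(read_id = character(0), sample_id = character(0),
               locus_id = character(0), cell_id = integer(0))
  list(reads = reads, read_map = read_map, truth = truth)
}

mutate_read <- function(read, rate) {
  n <- nchar(read)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(read)
  ch <- strsplit(read, "")[[1]]
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Write reads as FASTQ
#'
#' Constant-quality FASTQ output (the simulator does not model qualities).
#'
#' @param reads named character vector of read sequences.
#' @param path output file path.
#' @param quality_char quality character applied to every base.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  lines <- character(4L * length(reads))
  ids <- names(reads)
  lines[seq(1, length(lines), 4)] <- paste0("@", ids)
  lines[seq(2, length(lines), 4)] <- unname(reads)
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- strrep(quality_char, nchar(reads))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ/FASTA file into a named character vector
#'
#' @param path input file.
#' @param format `"fastq"` or `"fasta"`.
#' @return named character vector of sequences.
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  s <- Biostrings::readDNAStringSet(path, format = format)
  stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

# ---- synthetic reference construction ---------------------------------

#' Build a synthetic reference set and barcode table
#'
#' Constructs a circular plasmid and chromosome of random sequence, three
#' CRISPR loci with synthetic repeats/leader tails/pre-existing spacers, a
#' seed protospacer on the plasmid matching pre-existing spacer 1 of
#' CRISPR1 (with a TG escape PAM for priming, or GG for a targeted
#' plasmid), and per-sample barcodes. Everything is synthetic: no sequence
#' is taken from a real genome.
#'
#' @param seed RNG seed for reference construction.
#' @param plasmid_len,chrom_len replicon lengths (nt).
#' @param seed_pam PAM planted 3' of the seed protospacer on its strand:
#'   `"TG"` (escape, priming) or `"GG"` (consensus, targeted).
#' @param chrom_seed also plant a self-priming seed site on the chromosome
#'   (an escape-PAM target of a plasmid-derived spacer with chromosomal
#'   similarity); chromosomal captures then cluster around it.
#' @param samples character vector of sample ids to barcode.
#' @return list with `refset` (a [reference_set()]) and `barcode_table`.
#' @export
synthetic_references <- function(seed = 100L, plasmid_len = 5000L,
                                 chrom_len = 60000L, seed_pam = "TG",
                                 chrom_seed = FALSE, samples = "S1") {
  set.seed(seed)
  plasmid_seq <- random_dna(plasmid_len)
  pps_start <- as.integer(plasmid_len / 2)
  pps_end <- pps_start + 32L
  # seed protospacer on the minus strand; its PAM (3' on minus) sits at
  # plus [start-2, start): plant the reverse complement of the PAM there
  substr(plasmid_seq, pps_start - 1L, pps_start) <- rev_comp(seed_pam)
  plasmid <- replicon("pSim", plasmid_seq, "circular", "plasmid")
  chrom_dna <- random_dna(chrom_len)
  cps_start <- as.integer(chrom_len / 3)
  if (chrom_seed) {
    # self-priming site: escape TG PAM on the minus strand (deterministic
    # placement; consumes no extra randomness so the replicons match a
    # reference set built without it)
    substr(chrom_dna, cps_start - 1L, cps_start) <- rev_comp("TG")
  }
  chrom <- replicon("chrSim", chrom_dna, "circular", "chromosome")
  spacer1 <- fetch(plasmid, pps_start, pps_end, "-")

  weights <- c(CRISPR1 = 0.70, CRISPR2 = 0.28, CRISPR3 = 0.02)
  loci <- lapply(names(weights), function(id) {
    pre <- if (id == "CRISPR1") c(spacer1, random_dna(32)) else
      c(random_dna(32), random_dna(32))
    crispr_locus(id, repeat_seq = random_dna(28), leader_tail = random_dna(12),
                 preexisting_spacers = pre,
                 incorporation_weight = weights[[id]])
  })
  seed_sites <- data.frame(replicon_id = "pSim", start = pps_start,
                           end = pps_end, strand = "-",
                           kind = if (seed_pam == "GG") "targeted" else "priming",
                           stringsAsFactors = FALSE)
  if (chrom_seed) {
    seed_sites <- rbind(seed_sites,
                        data.frame(replicon_id = "chrSim", start = cps_start,
                                   end = cps_start + 32L, strand = "-",
                                   kind = "priming", stringsAsFactors = FALSE))
  }
  refset <- reference_set(list(plasmid, chrom), loci, seed_sites)

  barcode_table <- do.call(rbind, lapply(samples, function(s) {
    do.call(rbind, lapply(refset$loci, function(l) {
      data.frame(sample_id = s, locus_id = l$id, barcode5 = random_dna(8),
                 tag3 = l$preexisting_spacers[2], stringsAsFactors = FALSE)
    }))
  }))
  rownames(barcode_table) <- NULL
  list(refset = refset, barcode_table = barcode_table)
}
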