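#' Round-trip parameter recovery from a pipeline run
#'
#' Re-estimates the generative parameters of a simulation from the analysis
#' pipeline's output: slip-offset frequencies and GG-PAM fraction (read-
#' weighted, flip candidates excluded), the 32/33 nt length split among
#' canonical captures, locus weights, and -- when the truth sidecar is
#' supplied -- the PS+1 quadrant split relative to the PPS restricted to
#' arrays whose S+1 is the cell's first acquisition (identified through the
#' read-to-cell map), plus the sign fractions of PS+1->PS+2 and PPS->PS+2
#' travel distances on CRISPR1 arrays.
#'
#' @param pipeline result of [run_pipeline()].
#' @param refset the [reference_set()] used.
#' @param truth optional `AcquisitionTruth` from [simulate_population()].
#' @param read_map optional read-to-cell map from [emit_amplicons()].
#' @return list of estimates; each distribution comes with its supporting
#'   weight `n`.
#' @export
parameter_recovery <- function(pipeline, refset, truth = NULL,
                               read_map = NULL) {
  ann <- pipeline$annotated
  ann <- ann[ann$is_new & ann$status == "ok" & !ann$anomalous, , drop = FALSE]
  out <- list()

  called <- !is.na(ann$pam_category) & !(ann$flip_candidate %in% TRUE)
  cc <- ann[called, , drop = FALSE]
  w <- cc$read_count
  slip_lab <- ifelse(cc$slip_other, "other", as.character(cc$slip_offset))
  levels <- c(as.character(-3:3), "other")
  slip_freq <- vapply(levels, function(l) sum(w[slip_lab == l]), 0) / sum(w)
  out$slip_freq <- slip_freq
  out$slip_n <- sum(w)
  out$gg_fraction <- sum(w[cc$pam_category == "GG"]) / sum(w)

  l0 <- cc[!cc$slip_other & cc$slip_offset == 0L, , drop = FALSE]
  lens <- nchar(l0$spacer_seq)
  out$len32_fraction <- sum(l0$read_count[lens == 32L]) / sum(l0$read_count)
  out$len33_fraction <- sum(l0$read_count[lens == 33L]) / sum(l0$read_count)
  out$len_n <- sum(l0$read_count)

  lw <- tapply(ann$read_count, ann$locus_id, sum)
  out$locus_weights <- lw / sum(lw)
  out$locus_n <- sum(lw)

  pps <- refset$seed_sites[1, ]
  if (!is.null(truth) && !is.null(read_map) &&
      nrow(pipeline$read_assignments)) {
    ev <- truth$events
    first <- ev[ev$k == 1L & ev$mechanism %in% c("primed", "targeted"), ,
                drop = FALSE]
    locus1 <- stats::setNames(first$locus_id, first$cell_id)
    rm2 <- merge(read_map, pipeline$read_assignments, by = "read_id")
    rm2 <- rm2[!is.na(rm2$array_id), , drop = FALSE]
    eligible <- rm2[rm2$locus_id == locus1[as.character(rm2$cell_id)] &
                      !is.na(locus1[as.character(rm2$cell_id)]), ,
                    drop = FALSE]
    wt <- table(eligible$array_id)
    s1 <- ann[ann$s_index == 1L & !is.na(ann$strand) &
                !(ann$multi_locus %in% TRUE) &
                ann$array_id %in% names(wt), , drop = FALSE]
    if (nrow(s1)) {
      hits <- data.frame(replicon_id = s1$replicon_id,
                         mid = (s1$start + s1$end) / 2, strand = s1$strand,
                         read_count = as.numeric(wt[s1$array_id]))
      out$ps1_quadrants <- five_three_split(hits, pps, refset)
      out$ps1_n <- sum(hits$read_count)
    }
  }

  ord1 <- pipeline$ordered[pipeline$ordered$locus_id == "CRISPR1", ,
                           drop = FALSE]
  frac_pos <- function(d) {
    d <- d[d$distance != 0, , drop = FALSE]
    if (!nrow(d)) return(NA_real_)
    sum(d$weight[d$distance > 0]) / sum(d$weight)
  }
  d_ps12 <- pair_distances(ord1, pps, refset, "PS1", "PS2")
  d_pps2 <- pair_distances(ord1, pps, refset, "PPS", "PS2")
  out$frac_pos_ps1_ps2 <- frac_pos(d_ps12)
  out$frac_pos_pps_ps2 <- frac_pos(d_pps2)
  out$travel_n <- nrow(d_ps12)
  out
}
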