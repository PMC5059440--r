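#' Signed travel distance between two protospacers
#'
#' The anchor of a protospacer is its midpoint (plus-strand coordinates;
#' fractional for odd lengths). The distance is the shortest-arc separation
#' on circular replicons (linear separation otherwise). The sign is
#' positive iff the destination lies in the 5' direction of the origin,
#' evaluated on the destination's strand: on the plus strand 5' means
#' decreasing coordinate, on the minus strand increasing. Identical anchors
#' give 0; exact antipodes on circular replicons are undefined (NA).
#'
#' @param from_mid,to_mid anchor midpoints (plus coordinates).
#' @param to_strand strand of the destination protospacer.
#' @param L replicon length.
#' @param circular replicon topology flag.
#' @return signed distance in nt (vectorised; NA for antipodal ties).
#' @export
travel_distance <- function(from_mid, to_mid, to_strand, L, circular = TRUE) {
  if (circular) {
    delta <- (to_mid - from_mid) %% L
    delta <- ifelse(delta > L / 2, delta - L, delta)
    delta[abs(delta - L / 2) < 1e-9 | abs(delta + L / 2) < 1e-9] <- NA
  } else {
    delta <- to_mid - from_mid
  }
  ifelse(to_strand == "+", -delta, delta)
}

anchor_mid <- function(start, end, L) ((start + end) / 2) %% L

#' Ordered protospacer hits per array
#'
#' Joins array order (S+k) with mapping: per array, PS+k is the mapped hit
#' of the k-th acquired new spacer. Unmapped or multi-locus spacers keep
#' their k but carry NA coordinates (excluded from positional statistics
#' without renumbering). Anomalous arrays are dropped.
#'
#' @param annotated annotated spacer table from [annotate_spacers()].
#' @return data.frame of new spacers with `array_id`, `sample_id`,
#'   `locus_id`, `k`, `read_count`, `replicon_id`, `mid`, `strand`,
#'   `mapped`.
#' @export
order_hits <- function(annotated) {
  new <- annotated[annotated$is_new & !annotated$anomalous &
                     annotated$status == "ok", , drop = FALSE]
  mapped <- !is.na(new$start) & !(new$multi_locus %in% TRUE)
  data.frame(array_id = new$array_id, sample_id = new$sample_id,
             locus_id = new$locus_id, k = new$s_index,
             read_count = new$read_count,
             replicon_id = ifelse(mapped, new$replicon_id, NA),
             mid = ifelse(mapped, (new$start + new$end) / 2, NA),
             strand = ifelse(mapped, new$strand, NA),
             mapped = mapped, stringsAsFactors = FALSE)
}

#' Read-weighted strand fractions by acquisition order
#'
#' Per order index k, the read-weighted fraction of mapped protospacers on
#' the primed strand (the PPS strand) versus the non-primed (displaced)
#' strand.
#'
#' @param ordered output of [order_hits()], restricted as desired.
#' @param pps one-row seed site (from `refset$seed_sites`).
#' @param k_max largest order index to report.
#' @return data.frame `k`, `n_arrays`, `weight`, `frac_primed_strand`.
#' @export
strand_fraction_by_order <- function(ordered, pps, k_max = 5L) {
  oh <- ordered[ordered$mapped & ordered$replicon_id == pps$replicon_id &
                  ordered$k <= k_max, , drop = FALSE]
  out <- lapply(split(oh, oh$k), function(d) {
    data.frame(k = d$k[1L], n_arrays = nrow(d), weight = sum(d$read_count),
               frac_primed_strand =
                 sum(d$read_count[d$strand == pps$strand]) / sum(d$read_count))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(k = integer(0), n_arrays = integer(0),
                      weight = numeric(0), frac_primed_strand = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Strand x side proportions relative to the PPS
#'
#' Each mapped hit is assigned to one of four cells -- (primed or displaced
#' strand) x (5' or 3' of the PPS) -- by its strand and the sign of the
#' travel distance from the PPS; proportions are read-weighted. Antipodal
#' ties and zero distances are excluded.
#'
#' @param hits data.frame with `replicon_id`, `mid` (or `start`/`end`),
#'   `strand`, optional `read_count`.
#' @param pps one-row seed site.
#' @param refset a [reference_set()].
#' @return 2x2 matrix of proportions (rows: displaced/primed strand;
#'   columns: 5'/3').
#' @export
five_three_split <- function(hits, pps, refset) {
  rpl <- refset$replicons[[pps$replicon_id]]
  h <- hits[!is.na(hits$strand) & hits$replicon_id == pps$replicon_id, ,
            drop = FALSE]
  mid <- h$mid %||% ((h$start + h$end) / 2)
  pps_mid <- anchor_mid(pps$start, pps$end, rpl$length)
  d <- travel_distance(pps_mid, mid %% rpl$length, h$strand, rpl$length,
                       rpl$topology == "circular")
  w <- h$read_count %||% rep(1, nrow(h))
  keep <- !is.na(d) & d != 0
  strand_cell <- ifelse(h$strand == pps$strand, "primed", "displaced")
  side <- ifelse(d > 0, "5prime", "3prime")
  m <- matrix(0, 2, 2, dimnames = list(c("displaced", "primed"),
                                       c("5prime", "3prime")))
  for (i in which(keep)) m[strand_cell[i], side[i]] <- m[strand_cell[i], side[i]] + w[i]
  if (sum(m) > 0) m <- m / sum(m)
  m
}

#' Travel distances of named protospacer pairs per array
#'
#' `"PPS"` denotes the seed site; `"PS1"`, `"PS2"`, ... denote PS+k. For a
#' pair (from, to) the distance is computed per array when both ends are
#' mapped on the seed replicon.
#'
#' @param ordered output of [order_hits()].
#' @param pps one-row seed site.
#' @param refset a [reference_set()].
#' @param from,to pair endpoints, e.g. `"PPS"`, `"PS1"`.
#' @return data.frame `array_id`, `distance`, `weight`.
#' @export
pair_distances <- function(ordered, pps, refset, from = "PPS", to = "PS1") {
  rpl <- refset$replicons[[pps$replicon_id]]
  L <- rpl$length
  circular <- rpl$topology == "circular"
  pps_mid <- anchor_mid(pps$start, pps$end, L)
  k_of <- function(lbl) as.integer(sub("^PS", "", lbl))
  oh <- ordered[ordered$mapped & ordered$replicon_id == pps$replicon_id, ,
                drop = FALSE]
  get_end <- function(d, lbl) {
    if (lbl == "PPS") {
      list(mid = pps_mid, strand = pps$strand, ok = TRUE)
    } else {
      i <- which(d$k == k_of(lbl))
      if (length(i) == 1L) list(mid = d$mid[i] %% L, strand = d$strand[i], ok = TRUE)
      else list(ok = FALSE)
    }
  }
  rows <- lapply(split(oh, oh$array_id), function(d) {
    a <- get_end(d, from)
    b <- get_end(d, to)
    if (!a$ok || !b$ok) return(NULL)
    data.frame(array_id = d$array_id[1L],
               distance = travel_distance(a$mid, b$mid, b$strand, L, circular),
               weight = d$read_count[1L], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(array_id = character(0), distance = numeric(0),
               weight = numeric(0))
  rownames(out) <- NULL
  out[!is.na(out$distance), , drop = FALSE]
}

#' Weighted 2-D histogram of two travel distances
#'
#' The two travels of `pair_spec` (e.g. PPS->PS+1 and PS+1->PS+2) are
#' computed per array; arrays providing both distances contribute their
#' read count to the corresponding 2-D bin.
#'
#' @param ordered output of [order_hits()].
#' @param pps one-row seed site.
#' @param refset a [reference_set()].
#' @param pair_spec list of two length-2 character vectors naming the
#'   travels, e.g. `list(c("PPS","PS1"), c("PS1","PS2"))`.
#' @param binwidth bin width in nt.
#' @return list with `x_breaks`, `y_breaks`, `counts` (matrix), `total`.
#' @export
travel_heatmap <- function(ordered, pps, refset,
                           pair_spec = list(c("PPS", "PS1"), c("PS1", "PS2")),
                           binwidth = 100) {
  d1 <- pair_distances(ordered, pps, refset, pair_spec[[1]][1], pair_spec[[1]][2])
  d2 <- pair_distances(ordered, pps, refset, pair_spec[[2]][1], pair_spec[[2]][2])
  j <- merge(d1, d2, by = "array_id", suffixes = c("_x", "_y"))
  L <- refset$replicons[[pps$replicon_id]]$length
  lim <- ceiling((L / 2) / binwidth) * binwidth
  breaks <- seq(-lim, lim, by = binwidth)
  counts <- matrix(0, length(breaks) - 1L, length(breaks) - 1L)
  if (nrow(j)) {
    ix <- findInterval(j$distance_x, breaks, rightmost.closed = TRUE)
    iy <- findInterval(j$distance_y, breaks, rightmost.closed = TRUE)
    for (r in seq_len(nrow(j))) {
      counts[ix[r], iy[r]] <- counts[ix[r], iy[r]] + j$weight_x[r]
    }
  }
  list(x_breaks = breaks, y_breaks = breaks, counts = counts,
       total = sum(counts))
}

#' Terminal-position statistic for chromosomal spacers
#'
#' Among arrays containing at least one chromosome-targeting new spacer,
#' the read-weighted fraction whose chromosomal spacer occupies the
#' leader-proximal position (position 1, i.e. the final acquisition), plus
#' the count of arrays with more than one chromosomal spacer.
#'
#' @param annotated annotated spacer table from [annotate_spacers()].
#' @return list with `fraction_terminal`, `n_arrays`,
#'   `n_multi_chromosomal` (`fraction_terminal` is NA when no array
#'   qualifies).
#' @export
terminal_position_stat <- function(annotated) {
  new <- annotated[annotated$is_new & !annotated$anomalous &
                     annotated$status == "ok", , drop = FALSE]
  per <- split(new, new$array_id)
  w_term <- w_all <- 0
  n_arrays <- n_multi <- 0L
  for (d in per) {
    chrom <- d$target_class == "chromosome"
    if (!any(chrom)) next
    n_arrays <- n_arrays + 1L
    if (sum(chrom) > 1L) n_multi <- n_multi + 1L
    w <- d$read_count[1L]
    w_all <- w_all + w
    if (any(d$position[chrom] == 1L)) w_term <- w_term + w
  }
  list(fraction_terminal = if (w_all > 0) w_term / w_all else NA_real_,
       n_arrays = n_arrays, n_multi_chromosomal = n_multi)
}
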