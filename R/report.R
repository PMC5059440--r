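#' Summary table of spacer counts
#'
#' Builds the experiment summary: per-locus spacer counts, per-target-class
#' counts and their percentages of the grand total, rounded half-away-from-
#' zero to 2 decimals. All percentages share one grand total (the
#' target-class total when available), so the two sections are directly
#' comparable. An all-zero input yields an empty table (no division by
#' zero).
#'
#' @param locus_counts named integer vector of spacers per CRISPR locus.
#' @param target_counts named integer vector of spacers per target class
#'   (plasmid/chromosome/unknown).
#' @param total grand total to compute percentages against; defaults to the
#'   target-class sum, else the locus sum.
#' @return data.frame `section`, `group`, `count`, `pct`.
#' @export
summary_table <- function(locus_counts = NULL, target_counts = NULL,
                          total = NULL) {
  if (is.null(total)) {
    total <- if (!is.null(target_counts) && sum(target_counts) > 0) {
      sum(target_counts)
    } else {
      sum(locus_counts)
    }
  }
  rows <- list()
  add <- function(section, counts) {
    if (is.null(counts) || sum(counts) == 0 || total == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, group = names(counts), count = as.numeric(counts),
      pct = round_half_away(100 * as.numeric(counts) / total, 2),
      stringsAsFactors = FALSE)
  }
  add("locus", locus_counts)
  add("target", target_counts)
  if (!length(rows)) {
    return(data.frame(section = character(0), group = character(0),
                      count = numeric(0), pct = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}

#' Spacer-count ratio between two experiments
#'
#' The efficiency ratio used to compare priming against naive adaptation:
#' plasmid-targeting spacer count of one experiment over another's.
#'
#' @param count_a,count_b spacer counts.
#' @return `count_a / count_b`.
#' @export
acquisition_ratio <- function(count_a, count_b) count_a / count_b

#' Tally an annotated spacer table
#'
#' Read-weighted counts per locus and per target class for new spacers,
#' plus unique-protospacer and unique-array diversity counts.
#'
#' @param annotated annotated spacer table from [annotate_spacers()].
#' @return list with `locus_counts`, `target_counts`,
#'   `unique_protospacers`, `unique_arrays`.
#' @export
tally_spacers <- function(annotated) {
  new <- annotated[annotated$is_new & annotated$status == "ok", , drop = FALSE]
  locus_counts <- tapply(new$read_count, new$locus_id, sum)
  target_counts <- tapply(new$read_count, new$target_class, sum)
  mapped <- new[!is.na(new$start), , drop = FALSE]
  list(locus_counts = locus_counts[!is.na(locus_counts)],
       target_counts = target_counts[!is.na(target_counts)],
       unique_protospacers = unique_protospacer_count(mapped),
       unique_arrays = length(unique(new$array_id)))
}

#' Sliding-window density track
#'
#' Read-weighted counts of hit anchors (midpoints) in a sliding window of
#' `window` nt advanced in `step` nt increments. On circular replicons the
#' windows wrap, and the number of windows is `ceiling(L / step)`. A window
#' larger than the replicon collapses to one full-replicon window.
#'
#' @param positions numeric anchor positions (plus coordinates, `[0, L)`).
#' @param weights per-anchor weights (e.g. read counts); default 1.
#' @param L replicon length.
#' @param window window size in nt (150 for plasmid-scale tracks, 3000 for
#'   chromosome-scale ones).
#' @param step window step in nt.
#' @param circular topology flag.
#' @return data.frame `window_start`, `value`.
#' @export
density_track <- function(positions, weights = NULL, L, window = 150L,
                          step = 10L, circular = TRUE) {
  if (is.null(weights)) weights <- base::rep(1, length(positions))
  if (window >= L) {
    return(data.frame(window_start = 0L, value = sum(weights)))
  }
  starts <- seq(0L, by = step, length.out = ceiling(L / step))
  nw <- length(starts)
  val <- numeric(nw)
  seq_idx <- function(lo, hi) if (lo > hi) integer(0) else lo:hi
  for (i in seq_along(positions)) {
    a <- positions[i] %% L
    # a window starting at s contains a iff (a - s) mod L < window, i.e.
    # s lies in the circular arc (a - window, a]
    b <- a - window
    i_hi <- min(floor(a / step), nw - 1)
    idx <- if (b >= 0) {
      seq_idx(floor(b / step) + 1, i_hi)
    } else if (circular) {
      c(seq_idx(0, i_hi), seq_idx(floor((b + L) / step) + 1, nw - 1))
    } else {
      seq_idx(0, i_hi)
    }
    val[idx + 1L] <- val[idx + 1L] + weights[i]
  }
  data.frame(window_start = starts, value = val)
}

#' Per-position base-composition deviation
#'
#' Observed base frequency minus the 25% uniform expectation, in percentage
#' points, per position, over spacers of one stated length.
#' Overrepresentation is positive; columns sum to zero.
#'
#' @param spacers character vector of spacer sequences.
#' @param length spacer length analysed (others are dropped).
#' @param from_pam_end index positions from the PAM-proximal end
#'   (position 1 = the base adjacent to the PAM) instead of the mapped 5'
#'   end.
#' @return 4 x `length` numeric matrix (rows A/C/G/T), in percentage points.
#' @export
composition_deviation <- function(spacers, length = 32L,
                                  from_pam_end = FALSE) {
  sp <- spacers[nchar(spacers) == length]
  if (!length(sp)) stop("no spacers of the requested length")
  m <- do.call(rbind, strsplit(sp, ""))
  if (from_pam_end) m <- m[, ncol(m):1, drop = FALSE]
  dev <- sapply(seq_len(ncol(m)), function(j) {
    f <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    100 * as.numeric(f) / nrow(m) - 25
  })
  rownames(dev) <- c("A", "C", "G", "T")
  colnames(dev) <- seq_len(ncol(dev))
  dev
}

#' Rarefaction (saturation) curves
#'
#' Subsamples the read-level multiset of items (protospacers or arrays)
#' without replacement at the given depths and reports the mean and s.d. of
#' the unique-item count over `m` subsamples. At full depth the unique
#' count equals the true unique count with zero s.d.
#'
#' @param items character vector: one entry per read (the item that read
#'   supports), or a unique-item vector with `counts`.
#' @param counts optional read counts aligned with `items`.
#' @param depths subsampling depths (capped at the total).
#' @param m subsamples per depth.
#' @return data.frame `depth`, `mean_unique`, `sd_unique`.
#' @export
rarefaction <- function(items, counts = NULL, depths, m = 10L) {
  pool <- if (is.null(counts)) items else
    base::rep(items, times = counts)
  N <- length(pool)
  depths <- pmin(depths, N)
  out <- lapply(depths, function(d) {
    u <- vapply(seq_len(m), function(i) {
      length(unique(pool[sample.int(N, d)]))
    }, 0L)
    data.frame(depth = d, mean_unique = mean(u), sd_unique = stats::sd(u))
  })
  do.call(rbind, out)
}

#' Detect density hotspots
#'
#' Maximal runs of at least `min_windows` consecutive windows whose value
#' reaches `min_fold` times the track baseline (the median over windows
#' with nonzero value, avoiding the zero-median degeneracy of sparse
#' chromosome tracks). On circular tracks runs may wrap.
#'
#' @param track data.frame from [density_track()].
#' @param min_fold fold-over-baseline threshold.
#' @param min_windows minimum run length in windows.
#' @param circular whether the first and last window are adjacent.
#' @return data.frame `start_window`, `end_window` (window-start
#'   coordinates, inclusive), `peak_window`, `peak_value`.
#' @export
hotspot_detection <- function(track, min_fold = 5, min_windows = 3L,
                              circular = TRUE) {
  empty <- data.frame(start_window = integer(0), end_window = integer(0),
                      peak_window = integer(0), peak_value = numeric(0))
  nz <- track$value[track$value > 0]
  if (!length(nz)) return(empty)
  baseline <- stats::median(nz)
  hot <- track$value >= min_fold * baseline
  if (!any(hot)) return(empty)
  n <- length(hot)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (circular && nrow(runs) > 1L && hot[1L] && hot[n]) {
    runs$end[1L] <- runs$end[nrow(runs)]          # wrapped run (end < start)
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  run_len <- ifelse(runs$end >= runs$start, runs$end - runs$start + 1L,
                    n - runs$start + 1L + runs$end)
  runs <- runs[run_len >= min_windows, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- if (runs$end[i] >= runs$start[i]) runs$start[i]:runs$end[i] else
      c(runs$start[i]:n, 1:runs$end[i])
    peak <- idx[which.max(track$value[idx])]
    data.frame(start_window = track$window_start[runs$start[i]],
               end_window = track$window_start[runs$end[i]],
               peak_window = track$window_start[peak],
               peak_value = track$value[peak])
  })
  do.call(rbind, out)
}

#' Clone-enrichment QC per sample
#'
#' Flags a sample when a single S+1 spacer sequence accounts for more than
#' `threshold` (strict) of the sample's read-weighted arrays -- the
#' signature of a population founded by an already-adapted clone.
#'
#' @param annotated annotated spacer table from [annotate_spacers()].
#' @param threshold share above which a sample is flagged (default 0.30).
#' @return data.frame `sample_id`, `top_s1_share`, `flagged`.
#' @export
replicate_qc <- function(annotated, threshold = 0.30) {
  s1 <- annotated[annotated$is_new & annotated$s_index == 1L &
                    annotated$status == "ok", , drop = FALSE]
  out <- lapply(split(s1, s1$sample_id), function(d) {
    shares <- tapply(d$read_count, d$spacer_seq, sum) / sum(d$read_count)
    data.frame(sample_id = d$sample_id[1L], top_s1_share = max(shares),
               flagged = max(shares) > threshold, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(sample_id = character(0), top_s1_share = numeric(0),
                      flagged = logical(0))
  }
  rownames(res) <- NULL
  res
}
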