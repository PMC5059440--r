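#' Classify a PAM dinucleotide
#'
#' Categories follow the convention that N stands for every nucleotide
#' excluding G: `GG`, `GN` (first base G), `NG` (second base G), `NN`.
#' Non-ACGT characters count as non-G and set the `degenerate` attribute.
#'
#' @param pam 2-nt string (vectorised).
#' @return character vector of categories.
#' @export
classify_pam <- function(pam) {
  if (any(nchar(pam) != 2L, na.rm = TRUE)) stop("PAM must be 2 nt")
  b1 <- substr(pam, 1L, 1L) == "G"
  b2 <- substr(pam, 2L, 2L) == "G"
  out <- ifelse(b1 & b2, "GG", ifelse(b1, "GN", ifelse(b2, "NG", "NN")))
  deg <- grepl("[^ACGT]", pam)
  out[deg & !is.na(out)] <- "NN"
  attr(out, "degenerate") <- deg
  out
}

#' Call the slip offset of a mapped protospacer
#'
#' The canonical PAM window is the 2 nt immediately 3' of the protospacer
#' on the protospacer strand. `GG` is searched at window offsets
#' s = -3..+3 (negative offsets overlap the protospacer 3' end); the call
#' is the smallest |s| with a GG, ties broken toward positive s (plus slips
#' produce correctly measured spacers, so they are the better-behaved
#' interpretation). No GG within the radius sets `other`.
#'
#' @param spacer the spacer sequence (only its last 3 nt are used).
#' @param flank3 5 nt immediately 3' of the protospacer on its strand.
#' @param radius search radius in nt (default 3).
#' @return list with `pam_category`, `slip_offset` (NA when `other`),
#'   `other`.
#' @export
call_slip <- function(spacer, flank3, radius = 3L) {
  tail3 <- substr(spacer, max(1L, nchar(spacer) - 2L), nchar(spacer))
  ctx <- paste0(formatC(tail3, width = 3L, flag = "-"), flank3)
  # canonical window occupies ctx positions 4..5 (1-based)
  offs <- seq(-radius, radius)
  hit <- vapply(offs, function(s) substr(ctx, 4L + s, 5L + s) == "GG", TRUE)
  if (!any(hit)) {
    return(list(pam_category = classify_pam(substr(ctx, 4L, 5L))[[1]],
                slip_offset = NA_integer_, other = TRUE))
  }
  cand <- offs[hit]
  best <- cand[order(abs(cand), -sign(cand))][1L]
  list(pam_category = classify_pam(substr(ctx, 4L, 5L))[[1]],
       slip_offset = as.integer(best), other = FALSE)
}

#' Flag a flip candidate
#'
#' A mapped protospacer is a flip candidate when a `CC` occurs with its
#' start at offsets -3..+1 relative to the protospacer 5' boundary (i.e.
#' within 3 nt either side of the 5' end) -- the footprint of a canonical
#' GG capture integrated in the reverse orientation. Flip candidates are
#' excluded from slip statistics.
#'
#' @param flank5 5 nt immediately 5' of the protospacer on its strand.
#' @param spacer the spacer sequence (only its first 3 nt are used).
#' @return logical flag.
#' @export
call_flip <- function(flank5, spacer) {
  ctx <- paste0(flank5, substr(spacer, 1L, 3L))
  # 5' boundary sits after ctx position 5; CC start offsets -3..+1 are
  # ctx positions 3..7
  any(vapply(3:7, function(i) substr(ctx, i, i + 1L) == "CC", TRUE))
}

#' Slip/flip calls for an annotated spacer table
#'
#' @param tab data.frame with `spacer_seq`, `flank5`, `flank3`.
#' @return data.frame with `pam_category`, `slip_offset`, `other`,
#'   `flip_candidate`.
#' @export
slipflip_calls <- function(tab) {
  n <- nrow(tab)
  out <- data.frame(pam_category = character(n), slip_offset = NA_integer_,
                    other = NA, flip_candidate = NA, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cs <- call_slip(tab$spacer_seq[i], tab$flank3[i])
    out$pam_category[i] <- cs$pam_category
    out$slip_offset[i] <- cs$slip_offset
    out$other[i] <- cs$other
    out$flip_candidate[i] <- call_flip(tab$flank5[i], tab$spacer_seq[i])
  }
  out
}

#' Cross-tabulate slip category against spacer length
#'
#' Flip candidates must be excluded beforehand. Also reports the fraction
#' of non-32 nt spacers whose PAM is canonical (slip 0).
#'
#' @param calls data.frame with `slip_offset`, `slip_other` (or `other`)
#'   and `spacer_seq` (lengths derived) or `length`; optional `read_count`
#'   weights.
#' @param weighted weight by `read_count` when present.
#' @return list with `table` (length x slip category contingency table) and
#'   `frac_non32_canonical`.
#' @export
crosstab_slip_length <- function(calls, weighted = TRUE) {
  len <- calls$length %||% nchar(calls$spacer_seq)
  other <- calls$slip_other %||% calls$other
  slip <- ifelse(other, "other", as.character(calls$slip_offset))
  w <- if (weighted && !is.null(calls$read_count)) calls$read_count else
    rep(1L, length(len))
  tab <- stats::xtabs(w ~ len + slip)
  non32 <- len != 32L
  frac <- if (any(non32)) {
    sum(w[non32 & !other & calls$slip_offset == 0L], na.rm = TRUE) /
      sum(w[non32])
  } else {
    NA_real_
  }
  list(table = tab, frac_non32_canonical = frac)
}

#' G-stretch PAM usage
#'
#' For each canonical-PAM hit whose GG lies inside a maximal reference
#' G-run of length >= 3 (on the protospacer strand), records which GG of
#' the run the canonical window occupies: the 5'-most one or a later one.
#' Returns usage fractions per run length.
#'
#' @param hits annotated spacer table rows with canonical PAM (slip 0):
#'   needs `replicon_id`, `start`, `end`, `strand`; optional `read_count`.
#' @param refset a [reference_set()].
#' @param weighted weight by `read_count` when present.
#' @return data.frame `run_length`, `n_5prime`, `n_other`, `frac_5prime`
#'   (empty when no hit sits in a G-run).
#' @export
gstretch_usage <- function(hits, refset, weighted = TRUE) {
  res <- list()
  for (i in seq_len(nrow(hits))) {
    rpl <- refset$replicons[[hits$replicon_id[i]]]
    strand <- hits$strand[i]
    # 12-nt strand-local window starting 4 nt 5' of the PAM
    if (strand == "+") {
      win <- fetch_padded(rpl, hits$end[i] - 4L, hits$end[i] + 8L, "+")
      pam_at <- 5L                        # window position of first PAM base
    } else {
      win <- fetch_padded(rpl, hits$start[i] - 8L, hits$start[i] + 4L, "-")
      pam_at <- 5L
    }
    ch <- strsplit(win, "")[[1]]
    if (!identical(ch[pam_at], "G") || !identical(ch[pam_at + 1L], "G")) next
    lo <- pam_at
    while (lo > 1L && ch[lo - 1L] == "G") lo <- lo - 1L
    hi <- pam_at + 1L
    while (hi < length(ch) && ch[hi + 1L] == "G") hi <- hi + 1L
    run_len <- hi - lo + 1L
    if (run_len < 3L) next
    w <- if (weighted && !is.null(hits$read_count)) hits$read_count[i] else 1L
    res[[length(res) + 1L]] <- data.frame(run_length = run_len,
                                          is_5prime = pam_at == lo, w = w)
  }
  if (!length(res)) {
    return(data.frame(run_length = integer(0), n_5prime = numeric(0),
                      n_other = numeric(0), frac_5prime = numeric(0)))
  }
  df <- do.call(rbind, res)
  agg <- lapply(split(df, df$run_length), function(d) {
    n5 <- sum(d$w[d$is_5prime])
    no <- sum(d$w[!d$is_5prime])
    data.frame(run_length = d$run_length[1L], n_5prime = n5, n_other = no,
               frac_5prime = n5 / (n5 + no))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
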