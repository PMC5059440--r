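#' Map a spacer to the reference replicons
#'
#' Exact search on both strands of every replicon, circular-aware
#' (occurrences spanning the origin are found). Each hit carries its
#' 0-based half-open plus-strand interval, strand (the strand whose 5'->3'
#' sequence equals the spacer), 5-nt flanks read from the reference on the
#' protospacer strand, and the PAM (first 2 nt of the 3' flank).
#'
#' @param spacer spacer sequence.
#' @param refset a [reference_set()].
#' @param max_mismatch Hamming rescue tolerance (default 0 = exact). Rescued
#'   hits (mismatch > 0) are flagged via `rescued` and should be excluded
#'   from PAM statistics.
#' @return data.frame of hits (possibly 0 rows): `spacer_seq`,
#'   `replicon_id`, `start`, `end`, `strand`, `flank5`, `flank3`, `pam`,
#'   `rescued`.
#' @export
map_spacer <- function(spacer, refset, max_mismatch = 0L) {
  n <- nchar(spacer)
  rows <- list()
  for (rpl in refset$replicons) {
    L <- rpl$length
    subject <- if (rpl$topology == "circular" && n <= L) {
      paste0(rpl$seq, substr(rpl$seq, 1L, min(n - 1L, L)))
    } else {
      rpl$seq
    }
    for (strand in c("+", "-")) {
      pat <- if (strand == "-") rev_comp(spacer) else spacer
      starts <- match_starts0(pat, subject, max_mismatch)
      starts <- starts[starts < L]
      exact <- if (max_mismatch > 0L) {
        e0 <- match_starts0(pat, subject, 0L)
        starts %in% e0[e0 < L]
      } else {
        rep(TRUE, length(starts))
      }
      for (j in seq_along(starts)) {
        s0 <- starts[j]
        ctx <- site_context(rpl, s0, s0 + n, strand)
        rows[[length(rows) + 1L]] <- data.frame(
          spacer_seq = spacer, replicon_id = rpl$id, start = s0,
          end = s0 + n, strand = strand, flank5 = ctx$flank5,
          flank3 = ctx$flank3, pam = substr(ctx$flank3, 1L, 2L),
          rescued = !exact[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(spacer_seq = character(0), replicon_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), flank5 = character(0),
                      flank3 = character(0), pam = character(0),
                      rescued = logical(0)))
  }
  do.call(rbind, rows)
}

#' Count unique protospacers
#'
#' Protospacers are grouped by unique (replicon, start, end, strand);
#' read counts and spacer identities are ignored.
#'
#' @param hits data.frame with `replicon_id`, `start`, `end`, `strand`.
#' @return integer count of distinct tuples.
#' @export
unique_protospacer_count <- function(hits) {
  if (!nrow(hits)) return(0L)
  length(unique(paste(hits$replicon_id, hits$start, hits$end, hits$strand)))
}

#' Classify spacer targets
#'
#' Per spacer: `plasmid`/`chromosome` by the replicon role of its hits,
#' `unknown` when it maps nowhere, `ambiguous` when it maps to replicons of
#' both roles (reported separately, excluded from plasmid/chromosome
#' tallies). Spacers hitting more than one location are flagged
#' `multi_locus` and are excluded from positional analyses.
#'
#' @param spacers character vector of (unique) spacer sequences.
#' @param hits data.frame of mapped hits (as from [map_spacer()], row-bound).
#' @param refset a [reference_set()] (for replicon roles).
#' @return data.frame `spacer_seq`, `target_class`, `n_hits`, `multi_locus`.
#' @export
classify_targets <- function(spacers, hits, refset) {
  roles <- vapply(refset$replicons, `[[`, "", "role")
  out <- data.frame(spacer_seq = spacers, target_class = "unknown",
                    n_hits = 0L, multi_locus = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(hits)) {
    sp <- split(hits, hits$spacer_seq)
    i <- match(names(sp), out$spacer_seq)
    cls <- vapply(sp, function(h) {
      r <- unique(roles[h$replicon_id])
      if (length(r) > 1L) "ambiguous" else r
    }, "")
    nh <- vapply(sp, nrow, 0L)
    ok <- !is.na(i)
    out$target_class[i[ok]] <- cls[ok]
    out$n_hits[i[ok]] <- nh[ok]
    out$multi_locus[i[ok]] <- nh[ok] > 1L
  }
  out
}

#' Annotate extracted spacers with mapping, PAM and slip/flip calls
#'
#' The per-spacer annotation table of the pipeline: one row per array
#' position, carrying the spacer, its order index (S+k), the mapped
#' protospacer (replicon, interval, strand, flanks, PAM) for uniquely
#' mapped spacers, the slip/flip call and the target class.
#'
#' @param spacer_table long spacer table from [extract_arrays()].
#' @param refset a [reference_set()].
#' @param max_mismatch rescue tolerance passed to [map_spacer()].
#' @return the input data.frame with mapping and call columns appended.
#' @export
annotate_spacers <- function(spacer_table, refset, max_mismatch = 0L) {
  uniq <- unique(spacer_table$spacer_seq)
  hit_list <- lapply(uniq, map_spacer, refset = refset,
                     max_mismatch = max_mismatch)
  hits <- do.call(rbind, hit_list)
  classes <- classify_targets(uniq, hits, refset)

  # unique single-location hits feed positional/PAM analyses
  single <- hits[ave(seq_len(nrow(hits)), hits$spacer_seq,
                     FUN = length) == 1L, , drop = FALSE]
  mi <- match(spacer_table$spacer_seq, single$spacer_seq)
  ci <- match(spacer_table$spacer_seq, classes$spacer_seq)

  out <- spacer_table
  out$target_class <- classes$target_class[ci]
  out$multi_locus <- classes$multi_locus[ci]
  out$replicon_id <- single$replicon_id[mi]
  out$start <- single$start[mi]
  out$end <- single$end[mi]
  out$strand <- single$strand[mi]
  out$flank5 <- single$flank5[mi]
  out$flank3 <- single$flank3[mi]
  out$pam <- single$pam[mi]
  out$rescued <- single$rescued[mi]

  mapped <- !is.na(out$pam) & !(out$rescued %in% TRUE)
  out$pam_category <- NA_character_
  out$slip_offset <- NA_integer_
  out$slip_other <- NA
  out$flip_candidate <- NA
  if (any(mapped)) {
    calls <- slipflip_calls(out[mapped, , drop = FALSE])
    out$pam_category[mapped] <- calls$pam_category
    out$slip_offset[mapped] <- calls$slip_offset
    out$slip_other[mapped] <- calls$other
    out$flip_candidate[mapped] <- calls$flip_candidate
  }
  out
}
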