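#' Demultiplex reads by exact terminal tags
#'
#' A read is assigned to a (sample, locus) iff its 5' barcode and 3' primer
#' tag both match exactly, after orientation correction (a reverse-
#' complemented read carrying valid tags is flipped and assigned). Reads
#' matching no barcode pair are rejected.
#'
#' @param reads named character vector of merged reads.
#' @param barcode_table data.frame with `sample_id`, `locus_id`, `barcode5`,
#'   `tag3`; the (barcode5, tag3) pairs must be unique.
#' @return list with `assigned` (data.frame `read_id`, `sample_id`,
#'   `locus_id`, `seq` -- oriented) and `stats` (`reads_in`,
#'   `reads_barcode_ok`).
#' @export
demultiplex <- function(reads, barcode_table) {
  key <- paste(barcode_table$barcode5, barcode_table$tag3)
  if (anyDuplicated(key)) stop("duplicate (barcode5, tag3) pairs across samples")
  ids <- names(reads) %||% as.character(seq_along(reads))
  rows <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    seq <- reads[[i]]
    hit <- which(startsWith(seq, barcode_table$barcode5) &
                 endsWith(seq, barcode_table$tag3))
    if (!length(hit)) {
      rc <- rev_comp(seq)
      hit <- which(startsWith(rc, barcode_table$barcode5) &
                   endsWith(rc, barcode_table$tag3))
      if (length(hit)) seq <- rc
    }
    if (length(hit) == 1L) {
      rows[[i]] <- data.frame(read_id = ids[i],
                              sample_id = barcode_table$sample_id[hit],
                              locus_id = barcode_table$locus_id[hit],
                              seq = seq, stringsAsFactors = FALSE)
    }
  }
  keep <- !vapply(rows, is.null, TRUE)
  assigned <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(read_id = character(0), sample_id = character(0),
               locus_id = character(0), seq = character(0))
  list(assigned = assigned,
       stats = c(reads_in = length(reads), reads_barcode_ok = sum(keep)))
}

#' Orient a read by its repeat
#'
#' If the repeat occurs (within `max_mismatch` substitutions) in the read's
#' reverse complement but not in the read itself, the reverse complement is
#' returned; a read containing the repeat in neither orientation is flagged
#' unoriented.
#'
#' @param read a read sequence.
#' @param repeat_seq the locus repeat.
#' @param max_mismatch Hamming tolerance for the repeat search.
#' @return list with `seq` and `oriented` (flag).
#' @export
orient_read <- function(read, repeat_seq, max_mismatch = 3L) {
  if (length(match_starts0(repeat_seq, read, max_mismatch))) {
    return(list(seq = read, oriented = TRUE))
  }
  rc <- rev_comp(read)
  if (length(match_starts0(repeat_seq, rc, max_mismatch))) {
    return(list(seq = rc, oriented = TRUE))
  }
  list(seq = read, oriented = FALSE)
}

#' Dereplicate reads by exact identity and length
#'
#' Exact-string clustering: identical reads collapse into one cluster whose
#' representative is the string itself and whose count is the member count.
#'
#' @param reads character vector of (oriented) reads.
#' @return data.frame with `seq` and `count`, ordered by decreasing count.
#' @export
dereplicate <- function(reads) {
  if (!length(reads)) return(data.frame(seq = character(0), count = integer(0)))
  tab <- table(reads)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$seq), , drop = FALSE]
}

#' Extract the spacer array from one read
#'
#' Repeat-anchored extraction: all non-overlapping repeat occurrences
#' (Hamming distance <= `max_mismatch`, substitutions only, resolved
#' greedily left-most) are located; the spacers are the inter-repeat
#' segments. Reads with fewer than two repeats are rejected; an inter-repeat
#' segment outside `[min_len, max_len]` flags the read malformed.
#'
#' @param read an oriented read.
#' @param repeat_seq the locus repeat.
#' @param max_mismatch Hamming tolerance (default 3).
#' @param min_len,max_len admissible spacer lengths (defaults 20 and 45,
#'   wide enough for the aberrant 25-40+ nt spacers seen in expanded
#'   arrays).
#' @return list with `spacers` (character, leader-proximal first),
#'   `n_repeats`, `status` (`"ok"`, `"no_array"` or `"malformed"`).
#' @export
extract_array <- function(read, repeat_seq, max_mismatch = 3L,
                          min_len = 20L, max_len = 45L) {
  w <- nchar(repeat_seq)
  starts <- match_starts0(repeat_seq, read, max_mismatch)
  # greedy left-most non-overlapping resolution
  sel <- integer(0)
  last_end <- -1L
  for (s in starts) {
    if (s >= last_end) {
      sel <- c(sel, s)
      last_end <- s + w
    }
  }
  if (length(sel) < 2L) {
    return(list(spacers = character(0), n_repeats = length(sel),
                status = "no_array"))
  }
  spacers <- substring(read, head(sel, -1L) + w + 1L, sel[-1L])
  lens <- nchar(spacers)
  status <- if (any(lens < min_len | lens > max_len)) "malformed" else "ok"
  list(spacers = spacers, n_repeats = length(sel), status = status)
}

#' Identify the new spacers of an array
#'
#' New spacers are the leader-proximal maximal prefix not matching any
#' pre-existing spacer (exact match). Within that prefix, S+1 is the most
#' leader-distal new spacer (the earliest acquisition), S-numbers ascending
#' toward the leader. A pre-existing spacer found leader-proximal to a new
#' one flags the array anomalous.
#'
#' @param spacers character vector, leader-proximal first.
#' @param preexisting character vector of the locus' pre-existing spacers.
#' @return list with `new_idx` (positions of new spacers in the array),
#'   `s_index` (integer vector aligned with `spacers`: S+k for new spacers,
#'   NA otherwise) and `anomalous` (flag).
#' @export
classify_new_spacers <- function(spacers, preexisting) {
  is_pre <- spacers %in% preexisting
  m <- if (any(is_pre)) which(is_pre)[1L] - 1L else length(spacers)
  anomalous <- any(!is_pre[seq_along(spacers) > m])
  s_index <- rep(NA_integer_, length(spacers))
  if (m > 0L) s_index[seq_len(m)] <- m:1L
  list(new_idx = seq_len(m), s_index = s_index, anomalous = anomalous)
}

#' Extract dereplicated arrays from demultiplexed reads
#'
#' Driver for the extraction stage: dereplicates the assigned reads of each
#' (sample, locus), extracts the spacer array of each cluster and classifies
#' new spacers against the locus' pre-existing spacers.
#'
#' @param assigned data.frame from [demultiplex()].
#' @param refset a [reference_set()] providing the locus definitions.
#' @param max_mismatch,min_len,max_len see [extract_array()].
#' @return list with `arrays` (data.frame: `array_id`, `sample_id`,
#'   `locus_id`, `read_count`, `n_spacers`, `n_new`, `anomalous`, `status`),
#'   `spacers` (long data.frame: one row per array position with
#'   `spacer_seq`, `position`, `is_new`, `s_index`), `read_assignments`
#'   (`read_id` to `array_id`), and `stats`.
#' @export
extract_arrays <- function(assigned, refset, max_mismatch = 3L,
                           min_len = 20L, max_len = 45L) {
  arrays <- list()
  spacer_rows <- list()
  assign_rows <- list()
  clusters <- 0L
  for (grp in split(assigned, paste(assigned$sample_id, assigned$locus_id))) {
    if (!nrow(grp)) next
    locus <- refset$loci[[grp$locus_id[1L]]]
    derep <- dereplicate(grp$seq)
    clusters <- clusters + nrow(derep)
    cluster_aid <- base::rep(NA_character_, nrow(derep))
    for (i in seq_len(nrow(derep))) {
      ex <- extract_array(derep$seq[i], locus$repeat_seq, max_mismatch,
                          min_len, max_len)
      if (ex$status == "no_array") next
      cls <- classify_new_spacers(ex$spacers, locus$preexisting_spacers)
      aid <- sprintf("%s|%s|%d", grp$sample_id[1L], grp$locus_id[1L],
                     length(arrays) + 1L)
      cluster_aid[i] <- aid
      arrays[[length(arrays) + 1L]] <- data.frame(
        array_id = aid, sample_id = grp$sample_id[1L],
        locus_id = grp$locus_id[1L], read_count = derep$count[i],
        n_spacers = length(ex$spacers), n_new = length(cls$new_idx),
        anomalous = cls$anomalous, status = ex$status,
        stringsAsFactors = FALSE)
      spacer_rows[[length(spacer_rows) + 1L]] <- data.frame(
        array_id = aid, sample_id = grp$sample_id[1L],
        locus_id = grp$locus_id[1L], read_count = derep$count[i],
        position = seq_along(ex$spacers), spacer_seq = ex$spacers,
        is_new = seq_along(ex$spacers) %in% cls$new_idx,
        s_index = cls$s_index, anomalous = cls$anomalous,
        status = ex$status, stringsAsFactors = FALSE)
    }
    aid_of_read <- cluster_aid[match(grp$seq, derep$seq)]
    assign_rows[[length(assign_rows) + 1L]] <- data.frame(
      read_id = grp$read_id, array_id = aid_of_read,
      stringsAsFactors = FALSE)
  }
  arrays <- if (length(arrays)) do.call(rbind, arrays) else
    data.frame(array_id = character(0), sample_id = character(0),
               locus_id = character(0), read_count = integer(0),
               n_spacers = integer(0), n_new = integer(0),
               anomalous = logical(0), status = character(0))
  spacers <- if (length(spacer_rows)) do.call(rbind, spacer_rows) else
    data.frame(array_id = character(0), sample_id = character(0),
               locus_id = character(0), read_count = integer(0),
               position = integer(0), spacer_seq = character(0),
               is_new = logical(0), s_index = integer(0),
               anomalous = logical(0), status = character(0))
  read_assignments <- if (length(assign_rows)) do.call(rbind, assign_rows) else
    data.frame(read_id = character(0), array_id = character(0))
  rownames(arrays) <- rownames(spacers) <- rownames(read_assignments) <- NULL
  new_sp <- spacers$spacer_seq[spacers$is_new]
  stats <- c(clusters = clusters, arrays_detected = nrow(arrays),
             spacers_total = sum(spacers$read_count[spacers$is_new]),
             spacers_unique = length(unique(new_sp)))
  list(arrays = arrays, spacers = spacers,
       read_assignments = read_assignments, stats = stats)
}
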