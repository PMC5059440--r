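#' Replicon constructor
#'
#' A replicon is a single named reference sequence (plasmid or chromosome)
#' with a topology. All coordinates in the package are 0-based, half-open on
#' the plus strand; on circular replicons an interval may run past the end
#' (`end > length`), meaning it wraps across the origin.
#'
#' @param id replicon label.
#' @param seq DNA string (A/C/G/T/N; lower case is accepted and uppercased).
#' @param topology `"circular"` or `"linear"`.
#' @param role `"plasmid"` or `"chromosome"`.
#' @return an object of class `Replicon`.
#' @export
replicon <- function(id, seq, topology = c("circular", "linear"),
                     role = c("plasmid", "chromosome")) {
  topology <- match.arg(topology)
  role <- match.arg(role)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("replicon '", id, "': empty sequence")
  if (grepl("[^ACGTN]", seq)) {
    stop("replicon '", id, "': sequence contains non-DNA characters")
  }
  structure(list(id = id, seq = seq, topology = topology, role = role,
                 length = nchar(seq)),
            class = "Replicon")
}

#' @export
print.Replicon <- function(x, ...) {
  cat(sprintf("Replicon '%s': %d nt, %s %s\n", x$id, x$length, x$topology,
              x$role))
  invisible(x)
}

#' CRISPR locus definition
#'
#' Holds the repeat, leader tail and pre-existing spacers of one CRISPR array
#' (CRISPR1-3 in the type I-F system modelled here), plus its relative
#' incorporation activity.
#'
#' @param id locus label, e.g. `"CRISPR1"`.
#' @param repeat_seq repeat sequence (>= 20 nt).
#' @param leader_tail sequence between the barcoded leader primer and the
#'   first repeat on the amplicon.
#' @param preexisting_spacers character vector of pre-existing spacers,
#'   leader-proximal first.
#' @param incorporation_weight relative share of new integrations going to
#'   this locus (normalised across loci when used).
#' @return an object of class `CrisprLocus`.
#' @export
crispr_locus <- function(id, repeat_seq, leader_tail = "",
                         preexisting_spacers = character(0),
                         incorporation_weight = 1) {
  repeat_seq <- toupper(repeat_seq)
  if (nchar(repeat_seq) < 20) stop("locus '", id, "': repeat shorter than 20 nt")
  structure(list(id = id, repeat_seq = repeat_seq,
                 leader_tail = toupper(leader_tail),
                 preexisting_spacers = toupper(preexisting_spacers),
                 incorporation_weight = incorporation_weight),
            class = "CrisprLocus")
}

#' @export
print.CrisprLocus <- function(x, ...) {
  cat(sprintf("CrisprLocus '%s': repeat %d nt, %d pre-existing spacer(s), weight %.2f\n",
              x$id, nchar(x$repeat_seq), length(x$preexisting_spacers),
              x$incorporation_weight))
  invisible(x)
}

#' Reference set
#'
#' Bundles replicons, CRISPR loci and seed sites (priming or targeted
#' protospacers). The seed-site PAM is read from the reference, immediately
#' 3' of the protospacer interval on the protospacer strand.
#'
#' @param replicons list of [replicon()] objects.
#' @param loci list of [crispr_locus()] objects.
#' @param seed_sites data.frame with columns `replicon_id`, `start`, `end`
#'   (0-based half-open; on circular replicons `start > end` is read as a
#'   wrap), `strand` (`"+"`/`"-"`), `kind` (`"priming"`/`"targeted"`). May be
#'   `NULL`.
#' @return an object of class `ReferenceSet`.
#' @export
reference_set <- function(replicons, loci = list(), seed_sites = NULL) {
  names(replicons) <- vapply(replicons, `[[`, "", "id")
  names(loci) <- vapply(loci, `[[`, "", "id")
  rs <- structure(list(replicons = replicons, loci = loci,
                       seed_sites = NULL),
                  class = "ReferenceSet")
  if (!is.null(seed_sites) && nrow(seed_sites)) {
    seed_sites$strand <- as.character(seed_sites$strand)
    rows <- lapply(seq_len(nrow(seed_sites)), function(i) {
      s <- seed_sites[i, ]
      rep <- rs$replicons[[s$replicon_id]]
      if (is.null(rep)) stop("seed site on unknown replicon '", s$replicon_id, "'")
      L <- rep$length
      start <- s$start
      end <- s$end
      if (start < 0 || start >= L) stop("seed site start out of bounds")
      if (end < start) {                      # wrap notation
        if (rep$topology != "circular") {
          stop("seed site start > end on linear replicon '", rep$id, "'")
        }
        end <- start + ((end - start) %% L)
      }
      if (rep$topology == "linear" && end > L) {
        stop("seed site end beyond linear replicon '", rep$id, "'")
      }
      len <- end - start
      if (!len %in% c(32L, 33L)) {
        stop("seed protospacer length must be 32 or 33 nt, got ", len)
      }
      pam <- if (s$strand == "+") {
        fetch(rep, end %% L, end %% L + 2L, "+")
      } else {
        fetch(rep, (start - 2L) %% L, (start - 2L) %% L + 2L, "-")
      }
      data.frame(replicon_id = rep$id, start = start, end = end,
                 strand = s$strand, pam = pam,
                 kind = as.character(s$kind), stringsAsFactors = FALSE)
    })
    rs$seed_sites <- do.call(rbind, rows)
  }
  rs
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf("ReferenceSet: %d replicon(s), %d CRISPR locus/loci, %d seed site(s)\n",
              length(x$replicons), length(x$loci),
              if (is.null(x$seed_sites)) 0L else nrow(x$seed_sites)))
  invisible(x)
}

#' Load references from FASTA plus a locus/seed configuration
#'
#' The configuration (a YAML file or an equivalent list) names every replicon
#' in the FASTA and supplies CRISPR locus definitions and seed sites, e.g.:
#'
#' ```yaml
#' replicons:
#'   pPriming: {topology: circular, role: plasmid}
#' loci:
#'   CRISPR1:
#'     repeat_seq: GTT...
#'     leader_tail: ACGT...
#'     preexisting_spacers: [AAA..., CCC...]
#'     incorporation_weight: 0.70
#' seed_sites:
#'   - {replicon_id: pPriming, start: 2500, end: 2532, strand: "-", kind: priming}
#' ```
#'
#' @param fasta_source path to a (multi-)FASTA file, or a named character
#'   vector of sequences.
#' @param locus_config path to a YAML file, or a list with elements
#'   `replicons`, `loci`, `seed_sites`.
#' @return a [reference_set()].
#' @export
load_references <- function(fasta_source, locus_config) {
  seqs <- if (is.character(fasta_source) && length(fasta_source) == 1L &&
              file.exists(fasta_source)) {
    s <- Biostrings::readDNAStringSet(fasta_source)
    stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
  } else {
    fasta_source
  }
  cfg <- if (is.character(locus_config)) yaml::read_yaml(locus_config) else locus_config

  reps <- lapply(names(cfg$replicons), function(id) {
    if (!id %in% names(seqs)) {
      stop("config names replicon '", id, "' absent from FASTA")
    }
    rc <- cfg$replicons[[id]]
    replicon(id, seqs[[id]], topology = rc$topology %||% "circular",
             role = rc$role %||% "plasmid")
  })

  loci <- lapply(names(cfg$loci %||% list()), function(id) {
    lc <- cfg$loci[[id]]
    crispr_locus(id, lc$repeat_seq, lc$leader_tail %||% "",
                 unlist(lc$preexisting_spacers %||% character(0)),
                 lc$incorporation_weight %||% 1)
  })

  ss <- NULL
  if (length(cfg$seed_sites %||% list())) {
    ss <- do.call(rbind, lapply(cfg$seed_sites, function(s) {
      data.frame(replicon_id = s$replicon_id, start = s$start, end = s$end,
                 strand = s$strand, kind = s$kind %||% "priming",
                 stringsAsFactors = FALSE)
    }))
  }
  reference_set(reps, loci, ss)
}

#' Extract a sequence interval from a replicon
#'
#' Circular-aware accessor. Intervals are 0-based, half-open in plus-strand
#' coordinates; on circular replicons `end` may exceed the replicon length,
#' in which case the extraction wraps across the origin. `strand = "-"`
#' returns the reverse complement of the plus-strand extraction.
#'
#' @param rep a [replicon()].
#' @param start,end 0-based half-open interval, `0 <= start < L`,
#'   `start <= end <= start + L`.
#' @param strand `"+"` or `"-"`.
#' @return the interval's sequence as a character scalar.
#' @export
fetch <- function(rep, start, end, strand = "+") {
  L <- rep$length
  if (start < 0 || start >= L) stop("fetch: start out of [0, L)")
  if (end < start) stop("fetch: end < start")
  if (end > L && rep$topology != "circular") {
    stop("fetch: interval beyond end of linear replicon '", rep$id, "'")
  }
  if (end - start > L) stop("fetch: interval longer than replicon")
  s <- if (end > L) {
    paste0(substr(rep$seq, start + 1L, L), substr(rep$seq, 1L, end - L))
  } else {
    substr(rep$seq, start + 1L, end)
  }
  if (strand == "-") rev_comp(s) else s
}

# fetch() that tolerates out-of-bounds flanks on linear replicons by padding
# with N; on circular replicons coordinates are reduced modulo L.
fetch_padded <- function(rep, start, end, strand = "+") {
  L <- rep$length
  if (rep$topology == "circular") {
    s0 <- start %% L
    return(fetch(rep, s0, s0 + (end - start), strand))
  }
  left <- max(0L, -start)
  right <- max(0L, end - L)
  core <- if (start + left >= end - right) "" else
    fetch(rep, start + left, end - right, "+")
  s <- paste0(strrep("N", left), core, strrep("N", right))
  if (strand == "-") rev_comp(s) else s
}

#' Scan a replicon for motif occurrences
#'
#' Returns all 0-based plus-strand start positions of `motif`, overlaps
#' included. A minus-strand scan reports the plus-strand start coordinate of
#' each interval whose minus-strand reading equals the motif (equivalently, a
#' plus-strand scan for the reverse complement). On circular replicons,
#' occurrences spanning the origin are included. `N` bases never match.
#'
#' @param rep a [replicon()].
#' @param motif DNA string over A/C/G/T.
#' @param strand `"+"` or `"-"`.
#' @return sorted integer vector of start positions in `[0, L)`.
#' @export
scan_motif_sites <- function(rep, motif, strand = "+") {
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must be over A/C/G/T")
  pat <- if (strand == "-") rev_comp(motif) else motif
  subject <- if (rep$topology == "circular" && rep$length > 1L) {
    paste0(rep$seq, substr(rep$seq, 1L, min(nchar(motif) - 1L, rep$length)))
  } else {
    rep$seq
  }
  starts <- match_starts0(pat, subject)
  sort(unique(starts[starts < rep$length]))
}
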