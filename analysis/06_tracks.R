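#!/usr/bin/env Rscript
# Positional views: sliding-window density tracks on the plasmid (150 nt
# window, 10 nt step, per strand, with the GG-site background) and on the
# chromosome (3000 nt window, 10 nt step), hotspot calls, rarefaction
# curves, spacer base-composition deviation, and the clone-enrichment QC.

suppressPackageStartupMessages(library(adaptscan))
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
dir.create("results/tracks", showWarnings = FALSE)

for (exp in c("priming", "naive")) {
  refs <- synthetic_references(seed = 42, chrom_seed = exp == "naive")
  plasmid <- refs$refset$replicons$pSim
  chrom <- refs$refset$replicons$chrSim
  ann <- read.delim(sprintf("results/%s_spacers.tsv", exp))
  hits <- ann[ann$is_new & !is.na(ann$start) & !(ann$multi_locus %in% TRUE), ]

  # plasmid tracks per strand + GG-site background
  pl_hits <- hits[hits$replicon_id == "pSim", ]
  for (strand in c("+", "-")) {
    h <- pl_hits[pl_hits$strand == strand, ]
    tr <- density_track((h$start + h$end) / 2, h$read_count, plasmid$length,
                        window = 150, step = 10)
    gg <- scan_motif_sites(plasmid, "GG", strand)
    bg <- density_track(gg, NULL, plasmid$length, window = 150, step = 10)
    tr$background_gg <- bg$value
    write_tsv(tr, sprintf("results/tracks/%s_plasmid_%s.tsv", exp,
                          if (strand == "+") "plus" else "minus"))
  }

  # chromosome track (both strands pooled) + hotspots
  ch <- hits[hits$replicon_id == "chrSim", ]
  tr_c <- density_track((ch$start + ch$end) / 2, ch$read_count, chrom$length,
                        window = 3000, step = 10)
  write_tsv(tr_c, sprintf("results/tracks/%s_chromosome.tsv", exp))
  hs <- hotspot_detection(tr_c, min_fold = 5, min_windows = 3)
  if (nrow(hs)) write_tsv(hs, sprintf("results/%s_chrom_hotspots.tsv", exp))
  cat(sprintf("%-9s chromosome hotspots: %d\n", exp, nrow(hs)))

  # rarefaction of unique protospacers and unique arrays
  key <- paste(hits$replicon_id, hits$start, hits$end, hits$strand)
  depths <- unique(round(seq(1, sum(hits$read_count), length.out = 12)))
  set.seed(7)
  rp <- rarefaction(key, hits$read_count, depths)
  rp$what <- "protospacers"
  arr <- ann[!duplicated(ann$array_id), ]
  ra <- rarefaction(arr$array_id, arr$read_count, depths)
  ra$what <- "arrays"
  write_tsv(rbind(rp, ra), sprintf("results/%s_rarefaction.tsv", exp))
  sat <- rp$mean_unique[nrow(rp)] / rp$mean_unique[nrow(rp) - 1]
  cat(sprintf("          protospacer rarefaction near saturation (last/prev %.3f)\n", sat))

  # composition deviation of 32 nt spacers, indexed from the PAM end
  dev <- composition_deviation(base::rep(hits$spacer_seq, hits$read_count),
                               32, from_pam_end = TRUE)
  write_tsv(data.frame(base = rownames(dev), dev, check.names = FALSE),
            sprintf("results/%s_composition_deviation.tsv", exp))
  cat(sprintf("          PAM-proximal base deviation: A %+.1f C %+.1f G %+.1f T %+.1f pp\n",
              dev["A", 1], dev["C", 1], dev["G", 1], dev["T", 1]))

  qc <- replicate_qc(ann)
  cat(sprintf("          clone-enrichment QC: top S+1 share %.2f (%s)\n",
              qc$top_s1_share, ifelse(qc$flagged, "FLAGGED", "ok")))
}
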