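#!/usr/bin/env Rscript
# Acquisition-order statistics for the primed and targeted experiments:
# per-order strand fractions, the strand x side split of PS+1, travel-
# distance heatmaps (PPS->PS+1 x PPS->PS+2 versus PS+1->PS+2), and the
# terminal-position statistic for chromosomal spacers.

suppressPackageStartupMessages(library(adaptscan))
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
dir.create("results/heatmaps", showWarnings = FALSE)

refs_for <- function(exp) {
  synthetic_references(seed = 42,
                       seed_pam = if (exp == "targeted") "GG" else "TG",
                       chrom_seed = exp == "naive")
}

for (exp in c("priming", "targeted")) {
  refs <- refs_for(exp)
  ann <- read.delim(sprintf("results/%s_spacers.tsv", exp))
  ordered <- order_hits(ann)
  pps <- refs$refset$seed_sites[1, ]

  sf <- strand_fraction_by_order(ordered[ordered$locus_id == "CRISPR1", ], pps)
  sf$experiment <- exp
  write_tsv(sf, sprintf("results/%s_strand_by_order.tsv", exp))
  cat(sprintf("%-9s primed-strand fraction by order: %s\n", exp,
              paste(sprintf("PS+%d %.2f", sf$k, sf$frac_primed_strand),
                    collapse = "  ")))

  s1 <- ordered[ordered$k == 1 & ordered$mapped, ]
  m <- five_three_split(s1, pps, refs$refset)
  write_tsv(data.frame(strand = rownames(m)[row(m)], side = colnames(m)[col(m)],
                       proportion = as.vector(m)),
            sprintf("results/%s_ps1_split.tsv", exp))
  cat(sprintf("          PS+1 displaced-5' share %.2f\n",
              m["displaced", "5prime"]))

  for (spec in list(list(c("PPS", "PS1"), c("PPS", "PS2")),
                    list(c("PPS", "PS1"), c("PS1", "PS2")))) {
    hm <- travel_heatmap(ordered, pps, refs$refset, spec)
    nm <- sprintf("results/heatmaps/%s_%s-%s_x_%s-%s.tsv", exp,
                  spec[[1]][1], spec[[1]][2], spec[[2]][1], spec[[2]][2])
    mat <- as.data.frame(hm$counts)
    names(mat) <- head(hm$y_breaks, -1)
    mat$x_break <- head(hm$x_breaks, -1)
    write_tsv(mat, nm)
  }
  d12 <- pair_distances(ordered, pps, refs$refset, "PS1", "PS2")
  dp2 <- pair_distances(ordered, pps, refs$refset, "PPS", "PS2")
  fp <- function(d) sum(d$weight[d$distance > 0]) / sum(d$weight)
  cat(sprintf("          positive travel: PS1->PS2 %.2f vs PPS->PS2 %.2f\n",
              fp(d12), fp(dp2)))
}

# chromosomal terminality is best seen in the naive experiment, where the
# chromosomal event rate was elevated
ann_n <- read.delim("results/naive_spacers.tsv")
st <- terminal_position_stat(ann_n)
cat(sprintf("naive     chromosomal spacers leader-proximal terminal: %.2f (%d arrays, %d multi)\n",
            st$fraction_terminal, st$n_arrays, st$n_multi_chromosomal))
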