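# Shared fixtures, built in code at test time.

# A tiny deterministic replicon with a known sequence for coordinate tests.
tiny_circular <- function(seq = "ACGTACGTAC") {
  replicon("tiny", seq, "circular", "plasmid")
}

# Moderate simulation shared by several test files; built once per session.
.sim_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.sim_cache$res)) {
    sr <- synthetic_references(seed = 42)
    cfg <- sim_config(n_cells = 1500, seed = 11)
    truth <- simulate_population(sr$refset, cfg)
    em <- emit_amplicons(truth, sr$refset, sr$barcode_table, "S1", cfg)
    pl <- run_pipeline(em$reads, sr$refset, sr$barcode_table)
    .sim_cache$res <- list(refs = sr, cfg = cfg, truth = truth, em = em,
                           pl = pl)
  }
  .sim_cache$res
}

# Independent Hamming-window search used as an oracle against the
# Biostrings-backed matcher.
hamming_starts0 <- function(pattern, subject, max_mm) {
  pw <- nchar(pattern)
  pv <- strsplit(pattern, "")[[1]]
  out <- integer(0)
  for (s in 0:(nchar(subject) - pw)) {
    win <- strsplit(substr(subject, s + 1, s + pw), "")[[1]]
    mm <- sum(win != pv | win == "N" | pv == "N")
    if (mm <= max_mm) out <- c(out, s)
  }
  out
}
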