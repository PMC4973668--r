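# Small in-code fixtures shared across test files.

# A toy genotype matrix from a dosage matrix; one population unless given.
toy_gm <- function(dosage, lg = "LG01", pos = NULL, pops = NULL,
                   dp = NULL, gq = NULL, qual = 99, mq = 60) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(pops)) pops <- rep("P1", n)
  genotype_matrix(
    samples = data.frame(id = sprintf("s%02d", seq_len(n)),
                         population = pops, stringsAsFactors = FALSE),
    sites = data.frame(lg = rep_len(lg, m), pos = pos,
                       qual = rep_len(qual, m), mq = rep_len(mq, m),
                       stringsAsFactors = FALSE),
    dosage = dosage, dp = dp, gq = gq)
}

# Two drift-differentiated populations sampled at a given F.
sim_two_pop <- function(F, n_sites, n_per_pop, seed,
                        layout = genome_layout(rep(1e7, 5)),
                        missing_rate = 0, ld_block_bp = 0) {
  model <- population_model(c("P1", "P2"), F)
  fr <- simulate_frequencies(model, n_sites, seed)
  sample_genotypes(fr, layout, n_per_pop, missing_rate = missing_rate,
                   ld_block_bp = ld_block_bp, seed = seed + 1)
}

# A synthetic table of valid nonoverlapping windows in genome order.
make_window_table <- function(n_lg, windows_per_lg, size = 1e5) {
  lg <- rep(sprintf("LG%02d", seq_len(n_lg)), each = windows_per_lg)
  start <- rep((seq_len(windows_per_lg) - 1) * size, n_lg)
  data.frame(lg = lg, start = start, end = start + size,
             n_sites = 1000L, fst = 0, dxy = 0, stringsAsFactors = FALSE)
}
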