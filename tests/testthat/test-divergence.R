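# Independent scalar implementation of the Weir & Cockerham (1984)
# two-population variance components, written formula by formula.
wc84_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  CV2 <- ((n1 - nbar)^2 + (n2 - nbar)^2) / r / nbar^2
  nc <- nbar * (1 - CV2 * r / (r - 1) * (r - 1) / r)  # = nbar - sum(n^2)/(r*nbar), rewritten
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

test_that("site variance components match the textbook formulas and limits", {
  # fixed difference: p = 1 vs p = 0, 10 diploids each
  s <- site_variance_components(rep(2L, 10), rep(0L, 10))
  expect_equal(s$fst, 1, tolerance = 1e-6)
  # identical populations: among-population component non-positive
  g <- c(0L, 1L, 2L, 1L, 0L, 1L)
  s2 <- site_variance_components(g, g)
  expect_lte(s2$a, 0)
  expect_lte(s2$fst, 0)
  # pop1: 8 ALT of 20 alleles (10 diploids), pop2: 16 ALT of 20
  g1 <- c(rep(1L, 8), 0L, 0L)           # p = 0.4, h = 0.8
  g2 <- c(rep(2L, 6), rep(1L, 4))       # p = 0.8, h = 0.4
  s3 <- site_variance_components(g1, g2)
  o <- wc84_oracle(10, 0.4, 0.8, 10, 0.8, 0.4)
  expect_equal(s3$a, unname(o["a"]))
  expect_equal(s3$b, unname(o["b"]))
  expect_equal(s3$c, unname(o["c"]))
  expect_equal(s3$fst, unname(o["a"] / sum(o)))
  # unbalanced sample sizes against the oracle
  g4 <- c(2L, 2L, 1L, 0L, 1L)           # n=5, p=0.6, h=0.4
  g5 <- c(0L, 0L, 1L)                   # n=3, p=1/6, h=1/3
  s4 <- site_variance_components(g4, g5)
  o2 <- wc84_oracle(5, 0.6, 0.4, 3, 1/6, 1/3)
  expect_equal(c(s4$a, s4$b, s4$c), unname(o2))
  expect_error(site_variance_components(c(1L, NA, NA), g), ">= 2 genotyped")
})

test_that("window makers enumerate the documented window sets", {
  lay <- genome_layout(1.5e6, "LG01")
  w <- sliding_windows(lay, size = 1e6, step = 1e5)
  expect_equal(nrow(w), 6L)
  expect_equal(w$start, seq(0, 5e5, by = 1e5))
  expect_true(all(w$end - w$start == 1e6))
  # linkage group shorter than the window size: one truncated window
  short <- sliding_windows(genome_layout(4e5, "LG01"), size = 1e6, step = 1e5)
  expect_equal(nrow(short), 1L)
  expect_equal(short$end, 4e5)
  # step = size gives a nonoverlapping tiling with consecutive bins
  t10 <- nonoverlapping_windows(genome_layout(1e6, "LG01"), size = 1e5)
  expect_equal(nrow(t10), 10L)
  expect_equal(t10$start %/% 1e5, 0:9)
  expect_error(sliding_windows(lay, size = 1e5, step = 2e5))
})

test_that("window divergence equals site-by-site accumulation", {
  set.seed(33)
  d <- matrix(sample(c(0:2, NA), 16 * 100, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 16, 100)
  gm <- toy_gm(d, pos = sort(sample.int(5e5, 100)),
               pops = rep(c("A", "B"), each = 8))
  w <- nonoverlapping_windows(genome_layout(5e5, "LG01"), size = 1e5,
                              min_sites = 1)
  res <- window_divergence(gm, "A", "B", w)
  for (k in seq_len(nrow(res))) {
    in_w <- gm$sites$pos - 1 >= res$start[k] & gm$sites$pos - 1 < res$end[k]
    A <- gm$dosage[gm$samples$population == "A", in_w, drop = FALSE]
    B <- gm$dosage[gm$samples$population == "B", in_w, drop = FALSE]
    sa <- sb <- sabc <- sdxy <- 0; nuse <- 0
    for (j in seq_len(ncol(A))) {
      if (sum(!is.na(A[, j])) < 2 || sum(!is.na(B[, j])) < 2) next
      s <- site_variance_components(A[, j], B[, j])
      sa <- sa + s$a; sabc <- sabc + s$a + s$b + s$c
      pA <- mean(A[, j], na.rm = TRUE) / 2; pB <- mean(B[, j], na.rm = TRUE) / 2
      sdxy <- sdxy + pA * (1 - pB) + pB * (1 - pA)
      nuse <- nuse + 1
    }
    expect_equal(res$n_sites[k], nuse)
    expect_equal(res$fst[k], sa / sabc)
    expect_equal(res$dxy[k], sdxy / nuse)
  }
})

test_that("degenerate windows follow the stated conventions", {
  # all sites monomorphic in both populations: DXY 0, FST undefined
  gm <- toy_gm(matrix(0L, 8, 5), pops = rep(c("A", "B"), each = 4))
  w <- nonoverlapping_windows(genome_layout(1e4, "LG01"), size = 1e4,
                              min_sites = 1)
  res <- window_divergence(gm, "A", "B", w)
  expect_equal(res$dxy, 0)
  expect_true(is.na(res$fst))
  # one fixed difference among monomorphic sites: DXY = 1 / n_sites
  d <- matrix(0L, 8, 5); d[1:4, 3] <- 2L
  res2 <- window_divergence(toy_gm(d, pops = rep(c("A", "B"), each = 4)),
                            "A", "B", w)
  expect_equal(res2$dxy, 1 / 5)
  # FST and DXY are symmetric in the two populations
  set.seed(7)
  d3 <- matrix(sample(0:2, 8 * 40, replace = TRUE), 8, 40)
  gm3 <- toy_gm(d3, pops = rep(c("A", "B"), each = 4))
  w3 <- nonoverlapping_windows(genome_layout(4e4, "LG01"), size = 2e4,
                               min_sites = 1)
  ab <- window_divergence(gm3, "A", "B", w3)
  ba <- window_divergence(gm3, "B", "A", w3)
  expect_equal(ab$fst, ba$fst)
  expect_equal(ab$dxy, ba$dxy)
})

test_that("genome FST averages nonnegative windows and flags degenerate input", {
  gm <- sim_two_pop(0.1, 4000, 10, seed = 55, layout = genome_layout(rep(2e6, 2)))
  est <- genome_fst(gm, "P1", "P2", layout = genome_layout(rep(2e6, 2)))
  w <- nonoverlapping_windows(genome_layout(rep(2e6, 2)), size = 1e5,
                              min_sites = 1)
  wd <- window_divergence(gm, "P1", "P2", w)
  expect_equal(est, mean(wd$fst[is.finite(wd$fst) & wd$fst >= 0]))
  # identical "populations" give no positive windows
  half <- gm_subset(gm, sample_idx = which(gm$samples$population == "P1"))
  half$samples$population <- rep(c("X", "Y"), 5)
  expect_true(is.na(suppressWarnings(
    genome_fst(gm_subset(half, site_idx = 1:50), "X", "Y"))) ||
      suppressWarnings(genome_fst(gm_subset(half, site_idx = 1:50), "X", "Y")) < 0.05)
})

test_that("genome FST recovers the drift parameter", {
  gm <- sim_two_pop(0.1, 20000, 20, seed = 77)
  est <- genome_fst(gm, "P1", "P2")
  expect_gt(est, 0.08); expect_lt(est, 0.12)
})

test_that("sliding-window FST on low-drift data is right-skewed", {
  gm <- sim_two_pop(0.05, 8000, 8, seed = 99, layout = genome_layout(rep(1e7, 2)))
  sw <- sliding_windows(genome_layout(rep(1e7, 2)), size = 1e6, step = 1e5,
                        min_sites = 10)
  res <- window_divergence(gm, "P1", "P2", sw)
  x <- res$fst[is.finite(res$fst)]
  skew <- mean((x - mean(x))^3) / stats::sd(x)^3
  expect_gt(skew, 0)
})

test_that("p-distance follows the allelic mismatch rule", {
  gm <- toy_gm(rbind(c(0L, 1L, 2L, 1L), c(0L, 2L, 2L, 0L)))
  m <- p_distance_matrix(gm)
  expect_equal(m[1, 2], 0.25)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(s01 = 0, s02 = 0))
  # identical samples and opposite homozygotes
  gm2 <- toy_gm(rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L)))
  m2 <- p_distance_matrix(gm2, percent = TRUE)
  expect_equal(m2[1, 2], 0)
  expect_equal(m2[1, 3], 100)
  # no shared sites: undefined cell
  gm3 <- toy_gm(rbind(c(0L, NA), c(NA, 1L)))
  expect_true(is.na(p_distance_matrix(gm3)[1, 2]))
})
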