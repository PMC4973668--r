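test_that("VCF writing and reading round-trip the genotype content", {
  m <- population_model(c("P1", "P2"), 0.2)
  fr <- simulate_frequencies(m, 300, seed = 3)
  gm <- sample_genotypes(fr, genome_layout(rep(1e6, 2)), 5,
                         missing_rate = 0.1, seed = 4)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path, gm$samples)
  expect_equal(unname(back$dosage), unname(gm$dosage))
  expect_equal(back$sites$lg, gm$sites$lg)
  expect_equal(back$sites$pos, gm$sites$pos)
  expect_equal(back$samples$population, gm$samples$population)
  expect_equal(unname(back$dp), unname(gm$dp))
  expect_equal(unname(back$gq), unname(gm$gq))
  # write -> read -> write reproduces the file
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("one sample and one site produce one data line, masked cells ./.", {
  gm <- toy_gm(matrix(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  lines <- grep("^[^#]", readLines(path), value = TRUE)
  expect_length(lines, 1L)
  gm2 <- toy_gm(matrix(c(0L, NA), 1, 2))
  write_vcf(gm2, path)
  body <- grep("^[^#]", readLines(path), value = TRUE)
  expect_match(body[2], "\\./\\.")
  back <- read_vcf(path, gm2$samples)
  expect_identical(unname(back$dosage[1, ]), c(0L, NA))
})

test_that("sample subsetting and unmapped samples behave as specified", {
  m <- population_model("P1", 0.2)
  fr <- simulate_frequencies(m, 50, seed = 1)
  gm <- sample_genotypes(fr, genome_layout(1e6), c(P1 = 5), seed = 2)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  sub <- read_vcf(path, gm$samples, sample_subset = gm$samples$id[c(2, 4)])
  expect_equal(n_samples(sub), 2L)
  expect_equal(unname(sub$dosage), unname(gm$dosage[c(2, 4), ]))
  expect_error(read_vcf(path, gm$samples[-1, ]), "population map")
  expect_error(read_vcf("nonexistent.vcf", gm$samples), "no such file")
})

test_that("quality masks follow the threshold rules on a hand-traced toy", {
  # 3 samples x 3 sites; second site fails SNP quality, third fails MQ
  dp <- matrix(30, 3, 3); gq <- matrix(99, 3, 3)
  gm <- toy_gm(matrix(1L, 3, 3), qual = c(50, 19, 50), mq = c(60, 60, 19),
               dp = dp, gq = gq)
  out <- apply_quality_masks(gm)
  expect_equal(n_sites(out), 1L)
  expect_false(anyNA(out$dosage))

  # genotype-level: DP = 4 masks a cell, GQ = 19 masks another; at-threshold
  # values (DP = 5, GQ = 20) pass
  dp <- matrix(30, 3, 3); dp[1, 1] <- 4; dp[2, 2] <- 5
  gq <- matrix(99, 3, 3); gq[3, 3] <- 19; gq[2, 1] <- 20
  gm <- toy_gm(matrix(1L, 3, 3), dp = dp, gq = gq)
  out <- apply_quality_masks(gm)
  expect_equal(n_sites(out), 3L)
  expect_true(is.na(out$dosage[1, 1]))
  expect_false(is.na(out$dosage[2, 2]))
  expect_true(is.na(out$dosage[3, 3]))
  expect_false(is.na(out$dosage[2, 1]))

  gm_no_layers <- toy_gm(matrix(1L, 2, 2))
  expect_error(apply_quality_masks(gm_no_layers), "DP layer")
})

test_that("the high-depth rule uses each sample's own nearest-rank percentile", {
  n <- 1000
  dp <- matrix(30, 2, n)
  dp[1, 17] <- 10000                       # single outlier in sample 1
  gq <- matrix(99, 2, n)
  gm <- toy_gm(matrix(1L, 2, n), pos = seq_len(n) * 10, dp = dp, gq = gq)
  out <- apply_quality_masks(gm)
  expect_true(is.na(out$dosage[1, 17]))     # above sample 1's 99.5th percentile
  expect_identical(sum(is.na(out$dosage[2, ])), 0L)
  # uniform depth: nothing masked
  out2 <- apply_quality_masks(toy_gm(matrix(1L, 2, n), pos = seq_len(n) * 10,
                                     dp = matrix(30, 2, n), gq = matrix(99, 2, n)))
  expect_false(anyNA(out2$dosage))
})

test_that("site filters drop by missingness, MAF and allele count", {
  d <- matrix(1L, 8, 3)
  d[1:3, 1] <- NA                    # 3/8 missing > 0.25
  d[, 2] <- 0L                       # monomorphic
  gm <- toy_gm(d)
  out <- filter_sites(gm, max_missing_frac = 0.25, min_maf = 0.1)
  expect_equal(n_sites(out), 1L)
  expect_equal(out$sites$pos, gm$sites$pos[3])

  # identity when everything is off
  out2 <- filter_sites(gm, biallelic_only = FALSE, max_missing_frac = 1, min_maf = 0)
  expect_equal(n_sites(out2), 3L)

  # multi-allelic sites are dropped, never re-coded
  gm2 <- toy_gm(matrix(1L, 4, 2))
  gm2$sites$alt <- c("T", "T,G")
  expect_equal(n_sites(filter_sites(gm2)), 1L)

  expect_warning(filter_sites(gm, max_missing_frac = 0, min_maf = 0.9),
                 "no sites")
})

test_that("filtering is idempotent", {
  m <- population_model(c("P1", "P2"), 0.2)
  fr <- simulate_frequencies(m, 400, seed = 6)
  gm <- sample_genotypes(fr, genome_layout(rep(1e6, 2)), 8,
                         missing_rate = 0.15, seed = 7)
  once <- filter_sites(gm, max_missing_frac = 0.2, min_maf = 0.1)
  twice <- filter_sites(once, max_missing_frac = 0.2, min_maf = 0.1)
  expect_identical(twice, once)
  m1 <- apply_quality_masks(gm)
  m2 <- apply_quality_masks(m1)
  expect_identical(m2, m1)
})

test_that("distance thinning keeps the greedy leftmost set per linkage group", {
  gm <- toy_gm(matrix(1L, 2, 5), pos = c(1, 100001, 600001, 1000001, 1200001))
  out <- thin_by_distance(gm, min_bp = 5e5)
  expect_equal(out$sites$pos, c(1, 600001, 1200001))

  single <- thin_by_distance(toy_gm(matrix(1L, 2, 1), pos = 42), min_bp = 5e5)
  expect_equal(n_sites(single), 1L)

  two_lg <- toy_gm(matrix(1L, 2, 2), lg = c("LG01", "LG02"), pos = c(10, 20))
  expect_equal(n_sites(thin_by_distance(two_lg, min_bp = 5e5)), 2L)
})

test_that("thinning is idempotent and guarantees the pairwise distance", {
  m <- population_model("P1", 0.2)
  fr <- simulate_frequencies(m, 800, seed = 8)
  gm <- sample_genotypes(fr, genome_layout(rep(2e6, 3)), c(P1 = 4), seed = 9)
  direct <- thin_by_distance(gm, min_bp = 5e5)
  expect_identical(thin_by_distance(direct, min_bp = 5e5)$sites, direct$sites)
  for (out in list(direct,
                   thin_by_distance(thin_by_distance(gm, min_bp = 1e5), min_bp = 5e5))) {
    d <- diff(out$sites$pos)
    same_lg <- diff(match(out$sites$lg, unique(out$sites$lg))) == 0
    expect_true(all(d[same_lg] >= 5e5))
  }
})

test_that("SNAPP panel arithmetic satisfies stationarity and the printed rates", {
  r <- snapp_rates(0.5)
  expect_equal(r$u, 1); expect_equal(r$v, 1)
  # mean derived-allele frequency implied by a backward rate of 1.3420
  r2 <- snapp_rates(1 / (2 * 1.3420))
  expect_equal(round(r2$u, 4), 1.3420)
  expect_equal(round(r2$v, 4), 0.7969)
  expect_equal(r2$pi1 * r2$u + r2$pi0 * r2$v, 1, tolerance = 1e-12)
  expect_equal(r2$pi1, r2$v / (r2$u + r2$v), tolerance = 1e-12)
  expect_error(snapp_rates(0), "degenerate")
  expect_error(snapp_rates(1), "degenerate")
})

test_that("snapp_prepare thins, drops incomplete sites and reports the prior", {
  d <- rbind(c(1L, 2L, 0L, NA), c(1L, 0L, 0L, 1L))
  gm <- toy_gm(d, pos = c(1, 400001, 600001, 1200001))
  panel <- snapp_prepare(gm, min_bp = 5e5, alpha = 2, beta = 2000)
  # thinning keeps 1, 600001, 1200001; the last has a missing genotype
  expect_equal(panel$sites$pos, c(1, 600001))
  expect_equal(panel$n_sites, 2L)
  expect_equal(panel$pi1, mean(c(mean(c(1, 1)) / 2, mean(c(0, 0)) / 2)))
  expect_equal(panel$theta, 0.001)
  expect_equal(panel$pi1 * panel$u + panel$pi0 * panel$v, 1, tolerance = 1e-3)
  # all-reference panel is degenerate
  gm0 <- toy_gm(matrix(0L, 2, 2), pos = c(1, 600001))
  expect_error(snapp_prepare(gm0), "degenerate")
})
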