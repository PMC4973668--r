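#' Apply site- and genotype-level quality masks
#'
#' Reproduces the standard RAD-genotype filter cascade: sites failing the SNP
#' quality or mapping-quality thresholds are dropped; individual genotypes
#' failing the genotype-quality or depth rules are set to missing. All
#' quality comparisons pass at `value >= threshold`; the high-depth rule
#' passes at `DP <= cutoff`, where the cutoff is the nearest-rank percentile
#' of the sample's own non-missing per-site depth distribution.
#'
#' @param gm a [genotype_matrix()] with DP and GQ layers.
#' @param snp_qual minimum site QUAL.
#' @param geno_qual minimum per-genotype GQ.
#' @param map_qual minimum site mapping quality (MQ).
#' @param min_depth minimum per-genotype read depth.
#' @param high_depth_percentile per-sample depth percentile above which a
#'   genotype is masked (guards against collapsed repeats).
#' @return the masked [genotype_matrix()].
#' @export
apply_quality_masks <- function(gm, snp_qual = 20, geno_qual = 20,
                                map_qual = 20, min_depth = 5,
                                high_depth_percentile = 99.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$dp)) stop("DP layer required but absent")
  if (is.null(gm$gq)) stop("GQ layer required but absent")
  keep <- !is.na(gm$sites$qual) & gm$sites$qual >= snp_qual &
    !is.na(gm$sites$mq) & gm$sites$mq >= map_qual
  gm <- gm_subset(gm, site_idx = which(keep))
  dp <- gm$dp; gq <- gm$gq
  hi <- apply(dp, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(Inf)
    sort(v)[ceiling(high_depth_percentile / 100 * length(v))]
  })
  mask <- is.na(gq) | gq < geno_qual | is.na(dp) | dp < min_depth |
    dp > matrix(hi, nrow(dp), ncol(dp))
  gm$dosage[mask] <- NA_integer_
  gm
}

#' Filter sites on allele count, missingness and minor-allele frequency
#'
#' @param gm a [genotype_matrix()].
#' @param biallelic_only drop sites with multiple ALT alleles or indel
#'   alleles (never re-coded).
#' @param max_missing_frac maximum fraction of missing genotypes per site.
#' @param min_maf minimum minor-allele frequency, computed from non-missing
#'   dosages.
#' @return the filtered [genotype_matrix()]; an empty result is allowed and
#'   warns rather than errors.
#' @export
filter_sites <- function(gm, biallelic_only = TRUE, max_missing_frac = 1,
                         min_maf = 0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (max_missing_frac < 0 || max_missing_frac > 1 || min_maf < 0 || min_maf > 1)
    stop("thresholds must be in [0, 1]")
  bi <- !grepl(",", gm$sites$alt, fixed = TRUE) &
    nchar(gm$sites$ref) == 1L & nchar(gm$sites$alt) == 1L &
    gm$sites$alt %in% c("A", "C", "G", "T")
  miss <- colMeans(is.na(gm$dosage))
  n <- colSums(!is.na(gm$dosage))
  p <- ifelse(n > 0, colSums(gm$dosage, na.rm = TRUE) / (2 * n), NA_real_)
  maf <- pmin(p, 1 - p)
  maf_ok <- if (min_maf <= 0) rep(TRUE, n_sites(gm)) else !is.na(maf) & maf >= min_maf
  keep <- (!biallelic_only | bi) & miss <= max_missing_frac & maf_ok
  if (!any(keep)) warning("no sites pass the filters")
  gm_subset(gm, site_idx = which(keep))
}

#' Thin sites to a minimum pairwise distance
#'
#' Greedy left-to-right rule per linkage group: the first (leftmost) site is
#' kept; each subsequent site is kept iff its position minus the last kept
#' position is at least `min_bp`. Retained sites on one linkage group are
#' therefore pairwise at least `min_bp` apart; sites on different linkage
#' groups are never compared.
#'
#' @param gm a [genotype_matrix()] (sites are stored sorted).
#' @param min_bp minimum distance in bp between retained sites.
#' @return the thinned [genotype_matrix()].
#' @export
thin_by_distance <- function(gm, min_bp = 500000) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- logical(n_sites(gm))
  for (lg in unique(gm$sites$lg)) {
    idx <- which(gm$sites$lg == lg)
    last <- -Inf
    for (i in idx) {
      if (gm$sites$pos[i] - last >= min_bp) {
        keep[i] <- TRUE
        last <- gm$sites$pos[i]
      }
    }
  }
  gm_subset(gm, site_idx = which(keep))
}

#' Stationary forward/backward mutation rates for a SNP panel
#'
#' For a biallelic-substitution model at stationarity with unit total rate,
#' the backward rate `u` and forward rate `v` satisfy `pi1 * u + pi0 * v = 1`
#' and `pi1 = v / (u + v)`, giving `u = 1 / (2 * pi1)` and
#' `v = 1 / (2 * pi0)` where `pi1` is the mean derived (ALT) allele frequency
#' and `pi0 = 1 - pi1`.
#'
#' @param pi1 mean ALT allele frequency over the panel, in (0, 1).
#' @return list with elements `u`, `v`, `pi1`, `pi0`.
#' @export
snapp_rates <- function(pi1) {
  if (!is.finite(pi1) || pi1 <= 0 || pi1 >= 1)
    stop("degenerate panel: mean ALT frequency must be strictly in (0, 1)")
  list(u = 1 / (2 * pi1), v = 1 / (2 * (1 - pi1)), pi1 = pi1, pi0 = 1 - pi1)
}

#' Prepare an unlinked complete-data SNP panel for species-tree inference
#'
#' Thins sites to a minimum pairwise distance per linkage group (so markers
#' are effectively unlinked), removes any site with a missing genotype, and
#' computes the panel quantities used to parameterise coalescent SNP
#' species-tree analyses: the mean derived-allele frequency `pi1`, the
#' stationary unit-normalised mutation rates `u` and `v` (see
#' [snapp_rates()]), and the mean of the gamma prior on the population-size
#' parameter, `theta = alpha / beta`.
#'
#' @param gm a biallelic [genotype_matrix()].
#' @param min_bp minimum distance between retained SNPs on a linkage group.
#' @param alpha,beta gamma-prior shape and rate for theta.
#' @return object of class `snapp_panel`: retained site table, `n_sites`,
#'   `pi1`, `pi0`, `u`, `v`, `alpha`, `beta`, `theta`.
#' @export
snapp_prepare <- function(gm, min_bp = 500000, alpha = 2, beta = 2000) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(grepl(",", gm$sites$alt, fixed = TRUE)))
    stop("panel must be biallelic; run filter_sites(biallelic_only = TRUE)")
  gm <- thin_by_distance(gm, min_bp = min_bp)
  complete <- colSums(is.na(gm$dosage)) == 0L
  gm <- gm_subset(gm, site_idx = which(complete))
  if (n_sites(gm) == 0L) stop("no complete unlinked sites remain")
  pi1 <- mean(colMeans(gm$dosage) / 2)
  rates <- snapp_rates(pi1)
  structure(
    list(sites = gm$sites, n_sites = n_sites(gm), pi1 = rates$pi1,
         pi0 = rates$pi0, u = rates$u, v = rates$v, alpha = alpha,
         beta = beta, theta = alpha / beta),
    class = "snapp_panel"
  )
}

#' @export
print.snapp_panel <- function(x, ...) {
  cat(sprintf(
    "snapp_panel: %d unlinked complete sites\n  pi1 = %.4f, u = %.4f, v = %.4f\n  theta ~ Gamma(alpha = %g, rate = %g), mean theta = %g\n",
    x$n_sites, x$pi1, x$u, x$v, x$alpha, x$beta, x$theta
  ))
  invisible(x)
}
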