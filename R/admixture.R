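#' Per-site f4 statistic
#'
#' `(pA - pB) * (pC - pD)` on ALT allele frequencies, vectorised over sites.
#' Genetic drift is uncorrelated between unadmixed population pairs, so the
#' statistic has expectation zero under a tree without gene flow; positive
#' values imply flow between A-C and/or B-D. The same REF/ALT orientation is
#' used at every site for all populations (polarity flips only change the
#' site-wise sign and cancel in expectation).
#'
#' @param pA,pB,pC,pD allele-frequency vectors over the same sites.
#' @return numeric vector of per-site f4 values.
#' @export
site_f4 <- function(pA, pB, pC, pD) {
  (pA - pB) * (pC - pD)
}

#' Assign sorted sites to contiguous genomic blocks
#'
#' Tiles of `block_bp` per linkage group, anchored at the linkage-group
#' origin (position 1), so blocks never span linkage groups and block
#' membership is independent of which sites are present.
#'
#' @param sites data.frame with columns `lg` and `pos` (1-based), sorted.
#' @param block_bp block size in bp.
#' @return character vector of block labels, one per site.
#' @export
make_blocks <- function(sites, block_bp = 500000) {
  paste(sites$lg, (sites$pos - 1) %/% block_bp, sep = ":")
}

# Weighted delete-one-block jackknife variance (Busing et al. 1999) for a
# mean statistic with unequal block sizes m_j; reduces to the classical
# delete-one formula when all m_j are equal.
block_jackknife <- function(block_sums, block_n) {
  g <- length(block_n)
  n <- sum(block_n)
  theta <- sum(block_sums) / n
  theta_minus <- (sum(block_sums) - block_sums) / (n - block_n)
  h <- n / block_n
  theta_j <- g * theta - sum((1 - block_n / n) * theta_minus)
  pseudo <- h * theta - (h - 1) * theta_minus
  var_j <- mean((pseudo - theta_j)^2 / (h - 1))
  list(estimate = theta, se = sqrt(var_j), n_blocks = g, n = n)
}

#' Four-population (f4) admixture test with block jackknife
#'
#' Point estimate: the mean of per-site f4 values over usable sites (sites
#' where all four populations have at least `min_genotyped` genotyped
#' diploids). The standard error comes from a weighted delete-one-block
#' jackknife over contiguous genomic blocks (weights proportional to
#' per-block usable-site counts, so sparse blocks are handled correctly);
#' `Z = f4 / SEM` and the two-tailed p-value is computed with [z_to_p()].
#'
#' @param gm a [genotype_matrix()].
#' @param A,B,C,D population labels (pairs (A,B) and (C,D)).
#' @param block_bp jackknife block size in bp (matched to the scale at which
#'   linkage disequilibrium reaches background).
#' @param min_genotyped minimum genotyped diploids per population per site.
#' @return object of class `f4_result` with fields `pops`, `f4`, `sem`, `z`,
#'   `p`, `n_blocks`, `n_sites`.
#' @export
f4_test <- function(gm, A, B, C, D, block_bp = 500000, min_genotyped = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  st <- lapply(c(A, B, C, D), function(p) pop_site_stats(gm, p))
  usable <- st[[1]]$n >= min_genotyped & st[[2]]$n >= min_genotyped &
    st[[3]]$n >= min_genotyped & st[[4]]$n >= min_genotyped
  if (!any(usable)) stop("no sites usable in all four populations")
  f4s <- site_f4(st[[1]]$p, st[[2]]$p, st[[3]]$p, st[[4]]$p)[usable]
  blocks <- make_blocks(gm$sites[usable, , drop = FALSE], block_bp)
  bl <- factor(blocks, levels = unique(blocks))
  block_sums <- as.numeric(tapply(f4s, bl, sum))
  block_n <- as.numeric(tapply(f4s, bl, length))
  if (length(block_n) < 2)
    stop("fewer than 2 non-empty blocks: cannot estimate jackknife variance")
  jk <- block_jackknife(block_sums, block_n)
  if (jk$se > 0) {
    z <- jk$estimate / jk$se
    p <- z_to_p(z)
  } else if (jk$estimate == 0) {
    z <- 0; p <- 1
  } else {
    z <- sign(jk$estimate) * Inf; p <- 0
  }
  structure(
    list(pops = c(A = A, B = B, C = C, D = D), f4 = jk$estimate, sem = jk$se,
         z = z, p = p, n_blocks = jk$n_blocks, n_sites = jk$n),
    class = "f4_result"
  )
}

#' @export
print.f4_result <- function(x, ...) {
  cat(sprintf(
    "f4(%s, %s; %s, %s) = %.4g +/- %.4g (block-jackknife SEM)\nZ = %.3f, two-tailed p = %.3g  [%d sites in %d blocks]\n",
    x$pops["A"], x$pops["B"], x$pops["C"], x$pops["D"],
    x$f4, x$sem, x$z, x$p, x$n_sites, x$n_blocks
  ))
  invisible(x)
}

#' Two-tailed normal p-value from a Z-score
#'
#' `p = 2 * (1 - Phi(|z|))`, evaluated on the log scale of the normal tail so
#' at least two significant figures are retained down to p around 1e-300
#' (no premature underflow for the extreme Z-scores block-jackknife tests
#' produce).
#'
#' @param z finite Z-score (vectorised).
#' @return two-tailed p in (0, 1\].
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  pmin(1, exp(log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)))
}
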