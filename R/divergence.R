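# Weir & Cockerham (1984) variance components for a biallelic site and
# r = 2 populations, vectorised over sites. Inputs per population: number of
# genotyped diploids n, ALT allele frequency p, observed heterozygote
# frequency h. Sites with n < 2 in either population yield NA components.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  bad <- n1 < 2 | n2 < 2 | is.na(p1) | is.na(p2)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  a[bad] <- NA_real_; b[bad] <- NA_real_; c_[bad] <- NA_real_
  list(a = a, b = b, c = c_)
}

#' Weir-Cockerham variance components at one site
#'
#' The among-population (a), between-individual-within-population (b) and
#' within-individual (c) variance components of the Weir & Cockerham (1984)
#' FST estimator for a biallelic site and two populations; the site estimate
#' is `a / (a + b + c)` when the denominator is positive. `a` (and the
#' estimate) may be negative when populations are more similar than expected
#' under random mating.
#'
#' @param geno1,geno2 dosage vectors (0/1/2/NA) for the two populations;
#'   each must have at least 2 genotyped diploids.
#' @return list with components `a`, `b`, `c` and `fst`
#'   (`NA` when `a + b + c <= 0`).
#' @export
site_variance_components <- function(geno1, geno2) {
  n1 <- sum(!is.na(geno1)); n2 <- sum(!is.na(geno2))
  if (n1 < 2 || n2 < 2)
    stop("each population needs >= 2 genotyped diploids at the site")
  p1 <- mean(geno1, na.rm = TRUE) / 2
  p2 <- mean(geno2, na.rm = TRUE) / 2
  h1 <- mean(geno1 == 1L, na.rm = TRUE)
  h2 <- mean(geno2 == 1L, na.rm = TRUE)
  comp <- wc_components(n1, p1, h1, n2, p2, h2)
  denom <- comp$a + comp$b + comp$c
  list(a = comp$a, b = comp$b, c = comp$c,
       fst = if (is.finite(denom) && denom > 0) comp$a / denom else NA_real_)
}

#' Sliding-window index over a genome layout
#'
#' Half-open, 0-based windows `[start, start + size)` per linkage group,
#' starting at 0 with starts `step` apart. When a linkage group is at least
#' `size` long, only fully contained windows are emitted; a linkage group
#' shorter than `size` yields a single window truncated at its end.
#'
#' @param layout a [genome_layout()].
#' @param size window size in bp.
#' @param step slide length in bp (must not exceed `size`).
#' @param min_sites minimum usable sites per window, applied by
#'   [window_divergence()]; carried in the attribute `min_sites`.
#' @return data.frame (`lg`, `start`, `end`) of class `window_index`.
#' @export
sliding_windows <- function(layout, size = 1e6, step = 1e5, min_sites = 10000) {
  stopifnot(inherits(layout, "genome_layout"), size >= step)
  out <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length_bp[i]
    if (len >= size) {
      starts <- seq(0, len - size, by = step)
      data.frame(lg = layout$lg[i], start = starts, end = starts + size)
    } else {
      data.frame(lg = layout$lg[i], start = 0, end = len)
    }
  }))
  rownames(out) <- NULL
  attr(out, "min_sites") <- min_sites
  class(out) <- c("window_index", "data.frame")
  out
}

#' Nonoverlapping tiling windows
#'
#' @inheritParams sliding_windows
#' @return data.frame (`lg`, `start`, `end`) of class `window_index`.
#' @export
nonoverlapping_windows <- function(layout, size = 1e5, min_sites = 1000) {
  sliding_windows(layout, size = size, step = size, min_sites = min_sites)
}

# Derive a genome layout from the sites present in a matrix (lengths = max
# observed position per linkage group).
layout_from_sites <- function(gm) {
  len <- tapply(gm$sites$pos, gm$sites$lg, max)
  genome_layout(as.numeric(len), names(len))
}

#' Windowed relative (FST) and absolute (DXY) divergence
#'
#' Per window: FST is the ratio of summed Weir-Cockerham components,
#' `sum(a) / sum(a + b + c)` over usable sites (ratio of averages, stable at
#' low per-site information); DXY is the mean over usable sites of
#' `pA (1 - pB) + pB (1 - pA)`. A site is usable when both populations have
#' at least 2 genotyped diploids. Windows with fewer than the index's
#' `min_sites` usable sites (or the `min_sites` argument, if given) are
#' omitted.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population labels.
#' @param windows a window index from [sliding_windows()] or
#'   [nonoverlapping_windows()].
#' @param min_sites overrides the window index's `min_sites` when non-`NULL`.
#' @return data.frame (`lg`, `start`, `end`, `n_sites`, `fst`, `dxy`);
#'   windows are 0-based half-open.
#' @export
window_divergence <- function(gm, popA, popB, windows, min_sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(min_sites)) min_sites <- attr(windows, "min_sites")
  if (is.null(min_sites)) min_sites <- 1L
  sa <- pop_site_stats(gm, popA)
  sb <- pop_site_stats(gm, popB)
  comp <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
  usable <- !is.na(comp$a)
  dxy <- sa$p * (1 - sb$p) + sb$p * (1 - sa$p)
  a <- ifelse(usable, comp$a, 0)
  abc <- ifelse(usable, comp$a + comp$b + comp$c, 0)
  dxy0 <- ifelse(usable, dxy, 0)

  res <- windows
  res$n_sites <- 0L; res$fst <- NA_real_; res$dxy <- NA_real_
  pos0 <- gm$sites$pos - 1  # 0-based for half-open windows
  for (g in unique(windows$lg)) {
    sidx <- which(gm$sites$lg == g)
    widx <- which(windows$lg == g)
    if (!length(widx)) next
    p <- pos0[sidx]
    cs_n <- cumsum(c(0, usable[sidx]))
    cs_a <- cumsum(c(0, a[sidx]))
    cs_abc <- cumsum(c(0, abc[sidx]))
    cs_dxy <- cumsum(c(0, dxy0[sidx]))
    lo <- findInterval(windows$start[widx] - 0.5, p) + 1L
    hi <- findInterval(windows$end[widx] - 0.5, p)
    valid <- hi >= lo
    i1 <- lo[valid]; i2 <- hi[valid] + 1L
    ns <- cs_n[i2] - cs_n[i1]
    sum_a <- cs_a[i2] - cs_a[i1]
    sum_abc <- cs_abc[i2] - cs_abc[i1]
    sum_dxy <- cs_dxy[i2] - cs_dxy[i1]
    rows <- widx[valid]
    res$n_sites[rows] <- ns
    res$fst[rows] <- ifelse(sum_abc > 0, sum_a / sum_abc, NA_real_)
    res$dxy[rows] <- ifelse(ns > 0, sum_dxy / ns, NA_real_)
  }
  res <- res[res$n_sites >= max(1L, min_sites), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- "data.frame"
  res
}

#' Genome-wide FST between two populations
#'
#' The unweighted mean of per-window FST over nonoverlapping windows, after
#' removing windows with negative FST. Returns `NA` (with a warning) when no
#' window remains.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population labels.
#' @param layout optional [genome_layout()]; derived from the sites present
#'   when `NULL`.
#' @param window_size nonoverlapping window size in bp.
#' @param min_sites minimum usable sites per window.
#' @return scalar FST estimate (or `NA_real_`).
#' @export
genome_fst <- function(gm, popA, popB, layout = NULL, window_size = 1e5,
                       min_sites = 1) {
  if (is.null(layout)) layout <- layout_from_sites(gm)
  w <- nonoverlapping_windows(layout, size = window_size, min_sites = min_sites)
  wd <- window_divergence(gm, popA, popB, w)
  vals <- wd$fst[is.finite(wd$fst) & wd$fst >= 0]
  if (!length(vals)) {
    warning("no nonnegative windows; genome FST undefined")
    return(NA_real_)
  }
  mean(vals)
}

#' Uncorrected pairwise p-distance between samples
#'
#' Mean per-site allelic mismatch over jointly non-missing sites: a site
#' contributes `|d_i - d_j| / 2` for dosages `d` (0 for identical genotypes,
#' 0.5 for het vs hom, 1 for opposite homozygotes).
#'
#' @param gm a [genotype_matrix()] with >= 2 samples.
#' @param percent report distances x100.
#' @return symmetric matrix with zero diagonal, labelled by sample id; cells
#'   with no shared sites are `NA`.
#' @export
p_distance_matrix <- function(gm, percent = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"), n_samples(gm) >= 2)
  d <- gm$dosage
  n <- nrow(d)
  out <- matrix(0, n, n, dimnames = list(gm$samples$id, gm$samples$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[i, ]) & !is.na(d[j, ])
      out[i, j] <- out[j, i] <- if (any(ok)) {
        mean(abs(d[i, ok] - d[j, ok]) / 2)
      } else NA_real_
    }
  }
  if (percent) out <- out * 100
  out
}
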