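#' Squared genotype correlation between two sites
#'
#' Composite linkage disequilibrium for unphased diploid data: the squared
#' Pearson correlation of the 0/1/2 dosage vectors over pairwise-complete
#' samples. Returns `NA` (pair excluded, not an error) when fewer than
#' `min_complete` jointly non-missing samples remain or either site is
#' monomorphic among them.
#'
#' @param dosages_i,dosages_j dosage vectors over the same samples.
#' @param min_complete minimum jointly non-missing samples.
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
genotype_r2 <- function(dosages_i, dosages_j, min_complete = 2) {
  ok <- !is.na(dosages_i) & !is.na(dosages_j)
  if (sum(ok) < min_complete) return(NA_real_)
  x <- dosages_i[ok]; y <- dosages_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD decay profile within linkage groups, with cross-LG background
#'
#' Averages pairwise r-squared within distance bins for SNP pairs on the same
#' linkage group, and estimates the unlinked background as the mean r-squared
#' of pairs on different linkage groups. Pairs are uniformly subsampled
#' (seeded) when a bin exceeds `max_pairs_per_bin`. Sites on linkage groups
#' absent from `include_lgs` (e.g. unplaced scaffolds) can be excluded.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population whose samples are used (needs >= 4 samples).
#' @param bin_edges increasing bp breakpoints; bins are
#'   `[edge_k, edge_{k+1})`.
#' @param max_pairs_per_bin cap on pairs scored per bin.
#' @param max_background_pairs cap on cross-LG pairs for the background.
#' @param seed integer seed for the subsampling.
#' @param min_complete minimum jointly non-missing samples per pair.
#' @param include_lgs optional character vector restricting sites to these
#'   linkage groups.
#' @return object of class `ld_decay_profile`: data.frame `bins`
#'   (`bin_start`, `bin_end`, `mean_r2`, `n_pairs`), `background_r2`,
#'   `background_n`, `pop`.
#' @export
ld_decay <- function(gm, pop,
                     bin_edges = c(0, 1e4, 5e4, 1e5, 5e5, 1e6, 5e6),
                     max_pairs_per_bin = 5000, max_background_pairs = 5000,
                     seed = 1, min_complete = 4, include_lgs = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  rows <- which(gm$samples$population == pop)
  if (length(rows) < 4) stop("population needs >= 4 samples for LD estimation")
  if (!is.null(include_lgs)) {
    gm <- gm_subset(gm, site_idx = which(gm$sites$lg %in% include_lgs))
  }
  set.seed(as.integer(seed))
  d <- gm$dosage[rows, , drop = FALSE]
  lg <- gm$sites$lg
  pos <- gm$sites$pos
  maxd <- max(bin_edges)
  nb <- length(bin_edges) - 1L

  # enumerate within-LG pairs closer than max(bin_edges) via a two-pointer
  # scheme on the sorted positions
  pi_ <- integer(0); pj_ <- integer(0)
  for (g in unique(lg)) {
    idx <- which(lg == g)
    if (length(idx) < 2) next
    p <- pos[idx]
    jmax <- findInterval(p + maxd, p)  # last partner within maxd (p sorted)
    cnt <- pmax(0L, jmax - seq_along(p))
    if (sum(cnt) == 0) next
    i_loc <- rep(seq_along(p), cnt)
    j_loc <- i_loc + sequence(cnt)
    pi_ <- c(pi_, idx[i_loc]); pj_ <- c(pj_, idx[j_loc])
  }
  bins <- data.frame(bin_start = bin_edges[-(nb + 1L)], bin_end = bin_edges[-1L],
                     mean_r2 = NA_real_, n_pairs = 0L)
  if (length(pi_)) {
    dist <- abs(pos[pj_] - pos[pi_])
    bin <- findInterval(dist, bin_edges, rightmost.closed = FALSE)
    bin[dist >= maxd] <- NA
    for (b in seq_len(nb)) {
      sel <- which(bin == b)
      if (length(sel) > max_pairs_per_bin)
        sel <- sample(sel, max_pairs_per_bin)
      if (!length(sel)) next
      r2 <- vapply(sel, function(k)
        genotype_r2(d[, pi_[k]], d[, pj_[k]], min_complete), numeric(1))
      r2 <- r2[!is.na(r2)]
      bins$n_pairs[b] <- length(r2)
      bins$mean_r2[b] <- if (length(r2)) mean(r2) else NA_real_
    }
  }

  # cross-LG background
  background_r2 <- NA_real_; background_n <- 0L
  if (length(unique(lg)) >= 2) {
    n <- n_sites(gm)
    ii <- sample.int(n, 4 * max_background_pairs, replace = TRUE)
    jj <- sample.int(n, 4 * max_background_pairs, replace = TRUE)
    keep <- lg[ii] != lg[jj]
    ii <- ii[keep][seq_len(min(max_background_pairs, sum(keep)))]
    jj <- jj[keep][seq_len(min(max_background_pairs, sum(keep)))]
    r2 <- vapply(seq_along(ii), function(k)
      genotype_r2(d[, ii[k]], d[, jj[k]], min_complete), numeric(1))
    r2 <- r2[!is.na(r2)]
    background_n <- length(r2)
    background_r2 <- if (length(r2)) mean(r2) else NA_real_
  }
  structure(list(bins = bins, background_r2 = background_r2,
                 background_n = background_n, pop = pop),
            class = "ld_decay_profile")
}

#' @export
print.ld_decay_profile <- function(x, ...) {
  cat(sprintf("LD decay profile for population '%s'\n", x$pop))
  print(x$bins, row.names = FALSE)
  if (is.na(x$background_r2)) {
    cat("background (cross-LG): undefined (single linkage group)\n")
  } else {
    cat(sprintf("background (cross-LG): mean r2 = %.4f over %d pairs\n",
                x$background_r2, x$background_n))
  }
  invisible(x)
}

#' @export
plot.ld_decay_profile <- function(x, ...) {
  mid <- (x$bins$bin_start + x$bins$bin_end) / 2
  graphics::plot(mid / 1e3, x$bins$mean_r2, type = "b", log = "x",
                 xlab = "distance (kb)", ylab = expression(mean ~ r^2),
                 main = sprintf("LD decay: %s", x$pop), ...)
  if (!is.na(x$background_r2))
    graphics::abline(h = x$background_r2, lty = 2)
  invisible(x)
}

#' First distance bin at which LD decay reaches the unlinked background
#'
#' @param profile an [ld_decay()] result with a defined background.
#' @return one-row data.frame (`bin_start`, `bin_end`) of the first bin whose
#'   mean r-squared is at or below the background mean, or `NULL` if the
#'   profile never crosses it.
#' @export
background_crossing <- function(profile) {
  stopifnot(inherits(profile, "ld_decay_profile"))
  if (is.na(profile$background_r2))
    stop("profile has no background estimate (single linkage group?)")
  b <- profile$bins
  hit <- which(!is.na(b$mean_r2) & b$mean_r2 <= profile$background_r2)
  if (!length(hit)) return(NULL)
  b[hit[1], c("bin_start", "bin_end")]
}
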