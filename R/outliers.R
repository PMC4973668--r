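#' Flag the top-quantile FST outlier windows
#'
#' Flags the `ceiling(q * n)` highest-FST valid windows (nearest-rank rule).
#' Ties at the cutoff are broken by genome order (linkage group, then window
#' start) for determinism.
#'
#' @param window_stats data.frame from [window_divergence()] (valid windows
#'   only), in genome order, with an `fst` column.
#' @param q upper quantile in (0, 1), e.g. 0.01 or 0.05.
#' @return logical vector of outlier flags aligned to `window_stats` rows.
#' @export
top_quantile_windows <- function(window_stats, q) {
  n <- nrow(window_stats)
  if (n == 0L) stop("no valid windows")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  k <- ceiling(q * n)
  fst <- window_stats$fst
  fst[is.na(fst)] <- -Inf
  ord <- order(-fst, seq_len(n))  # rows are in genome order already
  flags <- logical(n)
  flags[ord[seq_len(k)]] <- TRUE
  flags
}

# Nearest-neighbour bin distances for a flagged subset; lg/bin vectors are
# over the flagged windows only. Flagged windows alone on their linkage
# group contribute no distance.
nn_distances <- function(lg, bin) {
  o <- order(lg, bin)
  l <- lg[o]; b <- bin[o]
  if (length(b) < 2) return(numeric(0))
  gaps <- diff(b)
  same <- diff(as.integer(factor(l, levels = unique(l)))) == 0
  gaps[!same] <- Inf
  nn <- pmin(c(Inf, gaps), c(gaps, Inf))
  nn[is.finite(nn)]
}

#' Nearest-neighbour distances between outlier windows
#'
#' For each outlier window with at least one other outlier on the same
#' linkage group, the minimum absolute difference of window bin numbers;
#' distances are never computed across linkage groups, and outliers alone on
#' their linkage group contribute nothing (their count is reported by
#' [nni_permutation_test()]).
#'
#' @param flags logical outlier flags over the valid windows.
#' @param lg linkage group per valid window.
#' @param bin per-linkage-group window bin number per valid window.
#' @return numeric vector of nearest-neighbour distances (possibly empty).
#' @export
nearest_neighbour_distances <- function(flags, lg, bin) {
  nn_distances(lg[flags], bin[flags])
}

#' Modified nearest-neighbour-index permutation test
#'
#' Tests whether outlier windows cluster along the genome. The observed
#' statistic is the mean nearest-neighbour bin distance between outliers
#' (within linkage groups only). Each permutation re-draws the same number
#' of outlier flags uniformly without replacement among all valid windows
#' genome-wide. The modified NNI divides the observed statistic by the mean
#' of the permuted statistics (rather than the classical points-per-length
#' expectation, which assumes a single linear genome); NNI < 1 indicates
#' clustering. `Z = (obs - mean(perm)) / sd(perm)`; the empirical p-value is
#' one-sided toward clustering with the +1 correction, and a two-sided
#' Z-based p is also reported. Permutation replicates whose outlier draw
#' yields no within-LG distances are excluded from the permutation mean/sd
#' and counted in `n_empty_perm`.
#'
#' @param windows data.frame of valid windows in genome order (`lg`,
#'   `start`, `end` columns as from [window_divergence()]).
#' @param flags logical outlier flags (at least 2 `TRUE`).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param window_size bin width in bp for converting starts to bin numbers;
#'   inferred as the maximum window span when `NULL`.
#' @return object of class `nni_result`.
#' @export
nni_permutation_test <- function(windows, flags, n_perm = 10000, seed = 1,
                                 window_size = NULL) {
  n <- nrow(windows)
  k <- sum(flags)
  if (k < 2) stop("need at least 2 outlier windows")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(window_size)) window_size <- max(windows$end - windows$start)
  lg <- as.integer(factor(windows$lg, levels = unique(windows$lg)))
  bin <- windows$start %/% window_size
  obs_d <- nearest_neighbour_distances(flags, lg, bin)
  n_lone <- k - length(obs_d)
  if (!length(obs_d)) stop("all outliers are alone on their linkage group")
  obs <- mean(obs_d)

  set.seed(as.integer(seed))
  perm <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    idx <- sample.int(n, k)
    d <- nn_distances(lg[idx], bin[idx])
    perm[r] <- if (length(d)) mean(d) else NA_real_
  }
  ok <- !is.na(perm)
  perm_mean <- mean(perm[ok])
  perm_sd <- stats::sd(perm[ok])
  nni <- obs / perm_mean
  if (is.na(perm_sd) || perm_sd == 0) {
    z <- NA_real_; p_z <- NA_real_
  } else {
    z <- (obs - perm_mean) / perm_sd
    p_z <- z_to_p(z)
  }
  p_emp <- (1 + sum(perm[ok] <= obs)) / (n_perm + 1)
  structure(
    list(n_outliers = k, n_lone_outliers = n_lone, obs_mean_nn = obs,
         perm_mean = perm_mean, perm_sd = perm_sd, nni = nni, z = z,
         p_emp = p_emp, p_z = p_z, n_perm = n_perm,
         n_empty_perm = sum(!ok), seed = as.integer(seed)),
    class = "nni_result"
  )
}

#' @export
print.nni_result <- function(x, ...) {
  cat(sprintf(
    "modified NNI test: %d outliers (%d alone on their LG)\n  observed mean NN distance = %.3f bins; permutation mean = %.3f (sd %.3f)\n  NNI = %.3f (%s), Z = %.3f, empirical p (clustering) = %.4g, Z-based p = %.4g\n  %d permutations (%d empty), seed %d\n",
    x$n_outliers, x$n_lone_outliers, x$obs_mean_nn, x$perm_mean, x$perm_sd,
    x$nni, if (is.na(x$nni)) "?" else if (x$nni < 1) "clustered" else "dispersed",
    x$z, x$p_emp, x$p_z, x$n_perm, x$n_empty_perm, x$seed
  ))
  invisible(x)
}

#' NNI clustering report over several comparisons and quantiles
#'
#' One row per comparison x outlier quantile: the top-quantile windows are
#' flagged with [top_quantile_windows()] and tested with
#' [nni_permutation_test()].
#'
#' @param comparisons named list of valid-window data.frames (one per
#'   population comparison), as from [window_divergence()] on nonoverlapping
#'   windows.
#' @param quantiles outlier quantiles, default top 0.01 and 0.05.
#' @param n_perm permutations per test.
#' @param seed integer master seed; each row gets a stable child seed.
#' @return data.frame with one row per comparison x quantile.
#' @export
nni_report_all <- function(comparisons, quantiles = c(0.01, 0.05),
                           n_perm = 10000, seed = 1) {
  rows <- list()
  for (nm in names(comparisons)) {
    for (q in quantiles) {
      ws <- comparisons[[nm]]
      flags <- top_quantile_windows(ws, q)
      r <- nni_permutation_test(ws, flags, n_perm = n_perm,
                                seed = stage_seed(seed, paste0("nni:", nm, ":", q)))
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = nm, quantile = q, n_outliers = r$n_outliers,
        obs_mean_nn = r$obs_mean_nn, perm_mean = r$perm_mean,
        perm_sd = r$perm_sd, nni = r$nni, z = r$z, p_emp = r$p_emp,
        p_z = r$p_z, n_perm = r$n_perm, seed = r$seed,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(comparison = character(0), quantile = numeric(0),
                      n_outliers = integer(0), obs_mean_nn = numeric(0),
                      perm_mean = numeric(0), perm_sd = numeric(0),
                      nni = numeric(0), z = numeric(0), p_emp = numeric(0),
                      p_z = numeric(0), n_perm = integer(0),
                      seed = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
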