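#' Vincenty inverse geodesic distance on the WGS84 ellipsoid
#'
#' Iterative inverse solution for the geodesic distance between two points
#' given in decimal degrees (WGS84: a = 6378137 m, f = 1/298.257223563).
#' Identical points return 0; the near-antipodal cases where the iteration
#' fails to converge raise an error (no fallback is implemented).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees
#'   (|lat| <= 90, |lon| <= 180).
#' @param tol convergence tolerance on the longitude-difference iterate,
#'   in radians.
#' @param max_iter maximum iterations.
#' @return distance in metres.
#' @export
vincenty_inverse <- function(lat1, lon1, lat2, lon2, tol = 1e-12,
                             max_iter = 200) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range")
  a <- 6378137
  f <- 1 / 298.257223563
  b <- a * (1 - f)
  rad <- pi / 180
  U1 <- atan((1 - f) * tan(lat1 * rad))
  U2 <- atan((1 - f) * tan(lat2 * rad))
  L <- (lon2 - lon1) * rad
  sinU1 <- sin(U1); cosU1 <- cos(U1)
  sinU2 <- sin(U2); cosU2 <- cos(U2)
  lambda <- L
  for (it in seq_len(max_iter)) {
    sinL <- sin(lambda); cosL <- cos(lambda)
    sinSigma <- sqrt((cosU2 * sinL)^2 + (cosU1 * sinU2 - sinU1 * cosU2 * cosL)^2)
    if (sinSigma == 0) return(0)  # coincident points
    cosSigma <- sinU1 * sinU2 + cosU1 * cosU2 * cosL
    sigma <- atan2(sinSigma, cosSigma)
    sinAlpha <- cosU1 * cosU2 * sinL / sinSigma
    cos2Alpha <- 1 - sinAlpha^2
    cos2SigmaM <- if (cos2Alpha == 0) 0 else cosSigma - 2 * sinU1 * sinU2 / cos2Alpha
    C <- f / 16 * cos2Alpha * (4 + f * (4 - 3 * cos2Alpha))
    lambda_new <- L + (1 - C) * f * sinAlpha *
      (sigma + C * sinSigma * (cos2SigmaM + C * cosSigma * (-1 + 2 * cos2SigmaM^2)))
    if (abs(lambda_new - lambda) < tol) {
      lambda <- lambda_new
      u2 <- cos2Alpha * (a^2 - b^2) / b^2
      A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
      B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
      dSigma <- B * sinSigma * (cos2SigmaM + B / 4 *
        (cosSigma * (-1 + 2 * cos2SigmaM^2) -
           B / 6 * cos2SigmaM * (-3 + 4 * sinSigma^2) * (-3 + 4 * cos2SigmaM^2)))
      return(b * A * (sigma - dSigma))
    }
    lambda <- lambda_new
  }
  stop("Vincenty iteration failed to converge (near-antipodal points)")
}

#' Pairwise geodesic distance matrix between sampling sites
#'
#' @param sites data.frame with columns `code`, `lat`, `lon` (decimal
#'   degrees).
#' @return symmetric matrix of distances in metres, labelled by site code,
#'   zero diagonal.
#' @export
geo_distance_matrix <- function(sites) {
  n <- nrow(sites)
  out <- matrix(0, n, n, dimnames = list(sites$code, sites$code))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- vincenty_inverse(sites$lat[i], sites$lon[i],
                                                 sites$lat[j], sites$lon[j])
    }
  }
  out
}

#' Perimeter distance along an ordered sequence of sites
#'
#' Sum of successive Vincenty legs in traversal order — e.g. the
#' along-the-shoreline distance between two sites through the intermediate
#' sampling locations.
#'
#' @param sites data.frame with columns `lat`, `lon`, at least 2 rows, in
#'   traversal order.
#' @return distance in metres.
#' @export
perimeter_distance <- function(sites) {
  n <- nrow(sites)
  if (n < 2) stop("need >= 2 sites in traversal order")
  sum(vapply(seq_len(n - 1), function(i)
    vincenty_inverse(sites$lat[i], sites$lon[i],
                     sites$lat[i + 1], sites$lon[i + 1]), numeric(1)))
}

#' Mantel test of matrix covariation
#'
#' Pearson correlation of the corresponding lower-triangle entries of two
#' distance matrices; the null distribution permutes the rows and columns of
#' the second matrix simultaneously. The empirical p-value is two-sided on
#' |r| with the +1 correction.
#'
#' @param matA,matB symmetric distance matrices with matching labels
#'   (n >= 3); `matB` is reordered to `matA`'s labels when both are
#'   labelled.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `mantel_result` with fields `r`, `p`, `n_perm`,
#'   `n`, `seed`.
#' @export
mantel_test <- function(matA, matB, n_perm = 9999, seed = 1) {
  matA <- as.matrix(matA); matB <- as.matrix(matB)
  n <- nrow(matA)
  if (n < 3) stop("need at least 3 labels")
  la <- rownames(matA); lb <- rownames(matB)
  if (!is.null(la) && !is.null(lb)) {
    if (!setequal(la, lb)) stop("matrix labels do not match")
    matB <- matB[la, la]
  } else if (!all(dim(matA) == dim(matB))) {
    stop("matrices must have matching dimensions")
  }
  lt <- lower.tri(matA)
  x <- matA[lt]; y <- matB[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- stats::cor(x, y)
  set.seed(as.integer(seed))
  count <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_p <- stats::cor(x, matB[idx, idx][lt])
    if (abs(r_p) >= abs(r_obs)) count <- count + 1L
  }
  structure(list(r = r_obs, p = (1 + count) / (n_perm + 1), n_perm = n_perm,
                 n = n, seed = as.integer(seed)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test: r = %.4f, two-sided empirical p = %.4g (%d labels, %d permutations, seed %d)\n",
    x$r, x$p, x$n, x$n_perm, x$seed
  ))
  invisible(x)
}
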