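#' Construct a genotype matrix
#'
#' The central container of the package: a diploid dosage matrix (samples x
#' sites) together with sample metadata (population labels) and site metadata
#' (linkage group, 1-based bp position, alleles, site quality, mapping
#' quality). Dosages count copies of the ALT allele and take values 0, 1, 2
#' or `NA` (missing). Optional per-genotype depth (DP) and genotype-quality
#' (GQ) layers carry the fields that genotype-level filters act on.
#'
#' Sites are stored sorted by (linkage group, position); positions must be
#' unique within a linkage group.
#'
#' @param samples data.frame with at least columns `id` and `population`
#'   (additional columns such as `species` or `site_code` are kept).
#' @param sites data.frame with columns `lg`, `pos` (1-based bp) and
#'   optionally `ref`, `alt`, `qual`, `mq` (defaults "A", "T", 99, 60).
#' @param dosage integer/numeric matrix, `nrow(samples)` x `nrow(sites)`,
#'   values in \{0, 1, 2, NA\}.
#' @param dp,gq optional matrices of the same dimension: per-genotype read
#'   depth and genotype quality.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, sites, dosage, dp = NULL, gq = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!all(c("id", "population") %in% names(samples)))
    stop("`samples` needs columns 'id' and 'population'")
  if (!all(c("lg", "pos") %in% names(sites)))
    stop("`sites` needs columns 'lg' and 'pos'")
  if (is.null(sites$ref)) sites$ref <- "A"
  if (is.null(sites$alt)) sites$alt <- "T"
  if (is.null(sites$qual)) sites$qual <- 99
  if (is.null(sites$mq)) sites$mq <- 60
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(sites))
    stop("dosage must be n_samples x n_sites")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  for (layer in list(dp = dp, gq = gq)) if (!is.null(layer)) {
    if (!identical(dim(as.matrix(layer)), dim(dosage)))
      stop("DP/GQ layers must match dosage dimensions")
  }
  ord <- order(sites$lg, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  if (!is.null(dp)) dp <- as.matrix(dp)[, ord, drop = FALSE]
  if (!is.null(gq)) gq <- as.matrix(gq)[, ord, drop = FALSE]
  dup <- duplicated(sites[, c("lg", "pos")])
  if (any(dup)) stop("duplicate positions within a linkage group")
  rownames(dosage) <- samples$id
  structure(
    list(samples = samples, sites = sites, dosage = dosage, dp = dp, gq = gq),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d sites on %d linkage group(s)\n",
    n_samples(x), n_sites(x), length(unique(x$sites$lg))
  ))
  tab <- table(x$samples$population)
  cat("populations:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("missing genotypes: %.2f%%; DP layer: %s; GQ layer: %s\n",
              100 * miss, !is.null(x$dp), !is.null(x$gq)))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$samples)

#' @rdname n_samples
#' @export
n_sites <- function(gm) nrow(gm$sites)

# Row/column subsetting that keeps all layers aligned.
gm_subset <- function(gm, sample_idx = NULL, site_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(n_samples(gm))
  if (is.null(site_idx)) site_idx <- seq_len(n_sites(gm))
  genotype_matrix(
    samples = gm$samples[sample_idx, , drop = FALSE],
    sites = gm$sites[site_idx, , drop = FALSE],
    dosage = gm$dosage[sample_idx, site_idx, drop = FALSE],
    dp = if (!is.null(gm$dp)) gm$dp[sample_idx, site_idx, drop = FALSE],
    gq = if (!is.null(gm$gq)) gm$gq[sample_idx, site_idx, drop = FALSE]
  )
}

# Per-site allele statistics for one population: number of genotyped
# diploids, ALT allele frequency, and observed heterozygote frequency.
pop_site_stats <- function(gm, pop) {
  rows <- which(gm$samples$population == pop)
  if (length(rows) == 0L) stop(sprintf("no samples in population '%s'", pop))
  d <- gm$dosage[rows, , drop = FALSE]
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}
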