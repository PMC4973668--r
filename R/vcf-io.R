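#' Write a genotype matrix to a VCF 4.2 file
#'
#' Emits one data line per site with site QUAL, mapping quality in
#' `INFO/MQ`, and per-genotype `GT:DP:GQ` (`GT` only when the matrix carries
#' no DP/GQ layers). Missing genotypes are written as `./.`. The output
#' round-trips losslessly through [read_vcf()].
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_sites(gm) == 0L || n_samples(gm) == 0L) stop("empty genotype matrix")
  has_layers <- !is.null(gm$dp) && !is.null(gm$gq)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popgenscan",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (has_layers) {
    header <- c(header,
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  }
  lg_len <- tapply(gm$sites$pos, gm$sites$lg, max)
  header <- c(header,
              sprintf("##contig=<ID=%s,length=%d>", names(lg_len),
                      as.integer(lg_len)),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples$id), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  d <- gm$dosage
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1L]
  if (has_layers) {
    dp <- ifelse(is.na(gm$dp), ".", as.character(gm$dp))
    gq <- ifelse(is.na(gm$gq), ".", as.character(gm$gq))
    cells <- matrix(paste(gt, dp, gq, sep = ":"), nrow(d), ncol(d))
  } else {
    cells <- gt
  }
  fixed <- paste(gm$sites$lg, as.integer(gm$sites$pos), ".", gm$sites$ref,
                 gm$sites$alt, gm$sites$qual, "PASS",
                 sprintf("MQ=%s", gm$sites$mq),
                 if (has_layers) "GT:DP:GQ" else "GT", sep = "\t")
  body <- do.call(paste, c(list(fixed), lapply(seq_len(nrow(d)), function(i) cells[i, ]),
                           list(sep = "\t")))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (via the vcfR package), converts diploid genotypes to ALT
#' dosages, and attaches population labels from a sample map. Half-calls
#' (e.g. `./1`) and genotypes carrying alleles beyond the first ALT are set
#' to missing and counted in `attr(, "flagged")`. The 1-based inclusive
#' coordinate convention of VCF is preserved in the site table.
#'
#' @param path VCF file path.
#' @param pop_map data.frame with columns `id`, `population`, or the path of
#'   a two-column TSV (sample, population).
#' @param sample_subset optional character vector of sample ids to keep.
#' @return a [genotype_matrix()] with DP/GQ layers when the VCF has them.
#' @export
read_vcf <- function(path, pop_map, sample_subset = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is.character(pop_map)) pop_map <- read_pop_map(pop_map)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, "GT")
  ids <- colnames(gt)
  if (!is.null(sample_subset)) {
    missing_ids <- setdiff(sample_subset, ids)
    if (length(missing_ids))
      stop("samples not in VCF: ", paste(missing_ids, collapse = ", "))
    ids <- sample_subset
    gt <- gt[, ids, drop = FALSE]
  }
  unmapped <- setdiff(ids, pop_map$id)
  if (length(unmapped))
    stop("samples missing from population map: ", paste(unmapped, collapse = ", "))

  fmt <- unique(vcf@gt[, "FORMAT"])
  has_dp <- all(grepl("DP", fmt))
  has_gq <- all(grepl("GQ", fmt))
  dp <- if (has_dp) vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)[, ids, drop = FALSE]
  gq <- if (has_gq) vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE)[, ids, drop = FALSE]

  code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
            "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dosage <- matrix(code[gt], nrow = nrow(gt))  # NA for ./. and anything else
  known_missing <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  flagged <- sum(is.na(dosage) & !known_missing)
  dosage <- t(dosage)  # samples x sites

  mq <- suppressWarnings(vcfR::extract.info(vcf, "MQ", as.numeric = TRUE))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  sites <- data.frame(lg = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      qual = qual, mq = if (is.null(mq)) NA_real_ else mq,
                      stringsAsFactors = FALSE)
  samples <- data.frame(id = ids,
                        population = pop_map$population[match(ids, pop_map$id)],
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(samples, sites, dosage,
                        dp = if (has_dp) t(dp), gq = if (has_gq) t(gq))
  attr(gm, "flagged") <- flagged
  gm
}

#' Read / write a sample-to-population map
#'
#' Two-column tab-separated text: sample id and population label, no header.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `population`.
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("id", "population"))
  df
}

#' @rdname read_pop_map
#' @param pop_map data.frame with columns `id`, `population`.
#' @export
write_pop_map <- function(pop_map, path) {
  utils::write.table(pop_map[, c("id", "population")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
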