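#' Define a multi-population drift model
#'
#' Describes the demography that the synthetic genotype generator draws from:
#' a set of populations related by a rooted split topology, each
#' differentiated from its ancestor by Balding-Nichols drift of strength `F`,
#' with optional single-pulse admixture edges applied at the allele-frequency
#' level.
#'
#' Under the Balding-Nichols model a population's allele frequency at a site
#' with ancestral frequency `p` is Beta(p(1-F)/F, (1-p)(1-F)/F), which has
#' mean `p` and gives an expected Weir-Cockerham FST of approximately `F`
#' between independently drifted populations.
#'
#' @param pops character vector of unique population labels.
#' @param drift_F per-population differentiation parameter in (0, 1);
#'   recycled if scalar.
#' @param topology optional rooted newick string over `pops` (e.g.
#'   `"((A,B),(C,D));"`). `NULL` means a star topology (all populations
#'   drift independently from the ancestor).
#' @param admix_edges list of admixture pulses, each
#'   `list(source = , target = , alpha = )` with `alpha` in \[0, 1\]: the
#'   target's frequency becomes `(1 - alpha) * own + alpha * source`.
#' @param ancestral_freq_range interval within (0, 1) from which ancestral
#'   frequencies are drawn uniformly.
#' @param internal_F drift applied on internal (non-leaf) branches of the
#'   topology. Shared internal drift moves sister populations together and
#'   cancels in four-population statistics.
#' @return An object of class `population_model`.
#' @export
population_model <- function(pops, drift_F, topology = NULL,
                             admix_edges = list(),
                             ancestral_freq_range = c(0.05, 0.95),
                             internal_F = 0.02) {
  pops <- as.character(pops)
  if (anyDuplicated(pops)) stop("population labels must be unique")
  drift_F <- rep_len(drift_F, length(pops))
  if (any(drift_F <= 0 | drift_F >= 1))
    stop("drift_F must be strictly in (0, 1)")
  if (internal_F < 0 || internal_F >= 1) stop("internal_F must be in [0, 1)")
  for (e in admix_edges) {
    if (!all(c("source", "target") %in% names(e)) || is.null(e$alpha))
      stop("admix edges need source, target and alpha")
    if (e$alpha < 0 || e$alpha > 1) stop("admixture proportion must be in [0, 1]")
    if (!all(c(e$source, e$target) %in% pops))
      stop("admix edge refers to unknown population")
  }
  r <- sort(ancestral_freq_range)
  if (r[1] <= 0 || r[2] >= 1) stop("ancestral_freq_range must lie within (0, 1)")
  tree <- NULL
  if (!is.null(topology)) {
    tree <- ape::read.tree(text = topology)
    if (is.null(tree)) stop("could not parse topology newick string")
    if (!setequal(tree$tip.label, pops) || length(tree$tip.label) != length(pops))
      stop("topology leaves must match the population labels exactly")
  }
  structure(
    list(pops = pops, drift_F = stats::setNames(drift_F, pops), tree = tree,
         admix_edges = admix_edges, ancestral_freq_range = r,
         internal_F = internal_F),
    class = "population_model"
  )
}

#' Define a genome layout
#'
#' Named linkage groups and their lengths in bp; all positions in the package
#' are 1-based and must fall within `[1, length]`.
#'
#' @param lg_lengths numeric vector of linkage-group lengths in bp (> 0).
#' @param lg_names optional identifiers; defaults to `LG01`, `LG02`, ...
#' @return data.frame of class `genome_layout` with columns `lg`, `length_bp`.
#' @export
genome_layout <- function(lg_lengths, lg_names = NULL) {
  if (any(lg_lengths <= 0)) stop("linkage-group lengths must be > 0")
  if (is.null(lg_names)) {
    lg_names <- names(lg_lengths)
    if (is.null(lg_names))
      lg_names <- sprintf("LG%02d", seq_along(lg_lengths))
  }
  if (anyDuplicated(lg_names)) stop("linkage-group names must be unique")
  out <- data.frame(lg = as.character(lg_names),
                    length_bp = as.numeric(lg_lengths),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

# One Balding-Nichols draw per site around parent frequency p.
bn_drift <- function(p, F) {
  if (F < 1e-12) return(p)
  out <- p
  ok <- p > 0 & p < 1
  if (any(ok)) {
    out[ok] <- stats::rbeta(sum(ok), p[ok] * (1 - F) / F,
                            (1 - p[ok]) * (1 - F) / F)
  }
  out
}

#' Simulate per-population allele frequencies
#'
#' Draws ancestral frequencies uniformly from the model's ancestral range and
#' propagates Balding-Nichols drift down the split topology (leaf branches use
#' the population's `drift_F`, internal branches the model's `internal_F`),
#' then applies admixture pulses in order.
#'
#' @param model a [population_model()].
#' @param n_sites number of independent sites to simulate.
#' @param seed integer seed; all randomness is derived from it.
#' @return numeric matrix (populations x sites) of ALT allele frequencies in
#'   \[0, 1\], with the ancestral frequencies in `attr(, "ancestral")`.
#' @export
simulate_frequencies <- function(model, n_sites, seed) {
  stopifnot(inherits(model, "population_model"), n_sites >= 1)
  set.seed(as.integer(seed))
  p_anc <- stats::runif(n_sites, model$ancestral_freq_range[1],
                        model$ancestral_freq_range[2])
  pops <- model$pops
  freq <- matrix(NA_real_, length(pops), n_sites, dimnames = list(pops, NULL))
  if (is.null(model$tree)) {
    for (pp in pops) freq[pp, ] <- bn_drift(p_anc, model$drift_F[[pp]])
  } else {
    tree <- ape::reorder.phylo(model$tree, "cladewise")
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    node_freq <- vector("list", ntip + tree$Nnode)
    node_freq[[root]] <- p_anc
    for (k in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[k, 1]
      child <- tree$edge[k, 2]
      F <- if (child <= ntip) model$drift_F[[tree$tip.label[child]]] else model$internal_F
      node_freq[[child]] <- bn_drift(node_freq[[parent]], F)
    }
    for (i in seq_len(ntip)) freq[tree$tip.label[i], ] <- node_freq[[i]]
  }
  for (e in model$admix_edges) {
    freq[e$target, ] <- (1 - e$alpha) * freq[e$target, ] + e$alpha * freq[e$source, ]
  }
  attr(freq, "ancestral") <- p_anc
  freq
}

#' Sample diploid genotypes from population frequencies
#'
#' Places sites uniformly over a genome layout, draws diploid ALT-dosages
#' `Binomial(2, p)` per individual, and optionally induces linkage
#' disequilibrium confined to blocks of `ld_block_bp`: within a block all
#' sites share one underlying frequency draw (the block's first site),
#' perturbed per site, and the two allele copies of each individual are
#' coupled through a shared block-level latent uniform with a per-site
#' refresh probability — so r-squared is elevated within a block and drops to
#' the unlinked background beyond the block span. Genotypes are masked
#' missing i.i.d. at `missing_rate`, and per-genotype depth and quality
#' layers plus site QUAL/MQ fields are emitted so downstream filters can be
#' exercised.
#'
#' @param freqs matrix from [simulate_frequencies()] (populations x sites).
#' @param layout a [genome_layout()].
#' @param n_per_pop diploids per population (scalar or named vector over the
#'   populations in `freqs`).
#' @param missing_rate i.i.d. missing-genotype probability in \[0, 1).
#' @param ld_block_bp LD block span in bp; 0 disables genotype-level linkage.
#' @param seed integer seed.
#' @param mean_depth mean simulated read depth (negative binomial).
#' @param ld_refresh per-site probability that an allele copy is redrawn
#'   independently of its block latent (controls within-block r-squared).
#' @param ld_freq_jitter sd of the per-site perturbation of the block
#'   frequency.
#' @return a [genotype_matrix()].
#' @export
sample_genotypes <- function(freqs, layout, n_per_pop, missing_rate = 0,
                             ld_block_bp = 0, seed = 1, mean_depth = 30,
                             ld_refresh = 0.3, ld_freq_jitter = 0.05) {
  stopifnot(inherits(layout, "genome_layout"))
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  pops <- rownames(freqs)
  if (is.null(pops)) stop("freqs must have population rownames")
  if (length(n_per_pop) == 1L) {
    n_per_pop <- stats::setNames(rep(n_per_pop, length(pops)), pops)
  }
  if (!setequal(names(n_per_pop), pops))
    stop("n_per_pop names must match the populations in freqs")
  n_per_pop <- n_per_pop[pops]
  set.seed(as.integer(seed))
  n_sites <- ncol(freqs)

  # site placement: linkage group proportional to length, positions uniform
  # without replacement, sorted
  lg_of <- sample(seq_len(nrow(layout)), n_sites, replace = TRUE,
                  prob = layout$length_bp)
  ord_lg <- order(layout$lg)
  sites_lg <- character(n_sites); sites_pos <- numeric(n_sites)
  freq_cols <- integer(n_sites)
  k <- 0L
  for (li in ord_lg) {
    cols <- which(lg_of == li)
    if (!length(cols)) next
    pos <- sort(sample.int(layout$length_bp[li], length(cols)))
    idx <- k + seq_along(cols)
    sites_lg[idx] <- layout$lg[li]
    sites_pos[idx] <- pos
    freq_cols[idx] <- cols
    k <- k + length(cols)
  }
  freqs <- freqs[, freq_cols, drop = FALSE]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- bases[((match(ref, bases) - 1 + sample.int(3, n_sites, replace = TRUE)) %% 4) + 1]
  sites <- data.frame(lg = sites_lg, pos = sites_pos, ref = ref, alt = alt,
                      qual = round(stats::runif(n_sites, 100, 2000), 1),
                      mq = pmin(60, round(stats::rnorm(n_sites, 58, 2), 1)),
                      stringsAsFactors = FALSE)

  block <- if (ld_block_bp > 0) {
    paste(sites_lg, (sites_pos - 1) %/% ld_block_bp)
  } else NULL

  n_tot <- sum(n_per_pop)
  dosage <- matrix(NA_integer_, n_tot, n_sites)
  row0 <- 0L
  for (pp in pops) {
    ni <- n_per_pop[[pp]]
    p <- freqs[pp, ]
    if (is.null(block)) {
      g <- matrix(stats::rbinom(ni * n_sites, 2, rep(p, each = ni)), nrow = ni)
    } else {
      first_in_block <- !duplicated(block)
      block_id <- match(block, block[first_in_block])
      p_block <- p[first_in_block][block_id]
      p_site <- pmin(1 - 1e-3, pmax(1e-3, p_block + stats::rnorm(n_sites, 0, ld_freq_jitter)))
      pm <- matrix(rep(p_site, each = ni), nrow = ni)
      g <- matrix(0L, ni, n_sites)
      for (copy in 1:2) {
        u_block <- matrix(stats::runif(ni * max(block_id)), nrow = ni)
        u <- u_block[, block_id, drop = FALSE]
        refresh <- matrix(stats::runif(ni * n_sites) < ld_refresh, nrow = ni)
        u[refresh] <- stats::runif(sum(refresh))
        g <- g + (u < pm)
      }
    }
    dosage[row0 + seq_len(ni), ] <- g
    row0 <- row0 + ni
  }

  if (missing_rate > 0) {
    dosage[stats::runif(length(dosage)) < missing_rate] <- NA_integer_
  }
  dp <- matrix(stats::rnbinom(n_tot * n_sites, mu = mean_depth, size = 8),
               n_tot, n_sites)
  gq <- matrix(pmax(0, pmin(99, round(stats::rnorm(n_tot * n_sites, 60, 18)))),
               n_tot, n_sites)
  samples <- data.frame(
    id = sprintf("%s_%02d", rep(pops, n_per_pop),
                 unlist(lapply(n_per_pop, seq_len), use.names = FALSE)),
    population = rep(pops, n_per_pop),
    stringsAsFactors = FALSE
  )
  genotype_matrix(samples, sites, dosage, dp = dp, gq = gq)
}
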