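# Synthetic binned contact matrices with planted structure.

#' Bin table tiling a genome at fixed resolution
#'
#' @param genome Named vector of chromosome lengths.
#' @param resolution Bin size in bp (the last bin of a chromosome may be
#'   short).
#' @return Data frame `bin_id`, `chrom`, `start`, `end`.
#' @export
make_bins <- function(genome, resolution) {
  out <- lapply(names(genome), function(chrom) {
    L <- genome[[chrom]]
    starts <- seq(0, L - 1, by = resolution)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + resolution, L))
  })
  bins <- do.call(rbind, out)
  bins <- cbind(bin_id = seq_len(nrow(bins)), bins)
  rownames(bins) <- NULL
  bins
}

# Family per bin under the same majority-overlap rule the analysis side
# uses (annotate_bins), so planted class effects line up exactly with
# measured classes.
.bin_true_family <- function(bins, isochores) {
  .majority_family(bins, isochores)
}

#' Simulate a binned Hi-C contact matrix with planted structure
#'
#' Intra-chromosomal matrices follow a Poisson law around a planted
#' expectation: `contact_base * |i - j|^-decay_exponent`, multiplied by
#' `domain_boost` when both bins fall in the same true isochore (the TAD
#' block signal) and by `gcpoor_longrange_boost` when both bins are
#' GC-poor (L1/L2), which produces the far-from-diagonal interactions of
#' GC-poor domains.
#'
#' Inter-chromosomal matrices plant the observed class preference among
#' interacting loci: each chromosome owns a fixed set of
#' `interchrom_hot_bins` "interactive" bins, of which a proportion
#' `interchrom_gcrich_preference` is GC-rich; `interchrom_hot_pairs`
#' hotspot pairs between the two chromosomes' interactive bins receive
#' `interchrom_hot_mu` extra expected counts over a uniform
#' `interchrom_base_mu` background. The interactive set of a chromosome
#' is derived from the config seed and the chromosome alone, so it is
#' identical across all pairs involving that chromosome.
#'
#' @param truth A `ground_truth`.
#' @param config The generating [sim_config()].
#' @param kind `"intra"` or `"inter"`.
#' @param chroms Chromosome name (intra) or pair of names (inter).
#' @return A [contact_matrix()].
#' @export
simulate_contact_matrix <- function(truth, config = truth$config,
                                    kind = c("intra", "inter"),
                                    chroms = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  kind <- match.arg(kind)
  if (kind == "intra") {
    chroms <- chroms %||% names(truth$genome)[1]
    stopifnot(length(chroms) == 1L)
    .simulate_intra(truth, config, chroms)
  } else {
    if (length(truth$genome) < 2L)
      stop("inter-chromosomal simulation needs at least 2 chromosomes")
    chroms <- chroms %||% names(truth$genome)[1:2]
    stopifnot(length(chroms) == 2L, chroms[1] != chroms[2])
    .simulate_inter(truth, config, chroms)
  }
}

.simulate_intra <- function(truth, config, chrom) {
  with_seed(stage_seed(config$seed, paste0("contacts-intra-", chrom)), {
    bins <- make_bins(truth$genome[chrom], config$contact_resolution)
    n <- nrow(bins)
    iso <- truth$isochores[truth$isochores$chrom == chrom, ]
    mid <- (bins$start + bins$end) / 2
    iso_idx <- findInterval(mid, iso$start)
    fam <- .bin_true_family(bins, iso)
    poor <- fam %in% .GC_POOR
    i <- rep(seq_len(n), times = n - seq_len(n) + 1L)
    j <- sequence(n - seq_len(n) + 1L) + i - 1L
    d <- j - i
    mu <- config$contact_base * ifelse(d == 0, 1, d^(-config$decay_exponent))
    mu <- mu * ifelse(iso_idx[i] == iso_idx[j], config$domain_boost, 1)
    mu <- mu * ifelse(poor[i] & poor[j], config$gcpoor_longrange_boost, 1)
    v <- stats::rpois(length(mu), mu)
    keep <- v > 0
    contact_matrix(bins,
                   data.frame(bin_i = i[keep], bin_j = j[keep],
                              value = v[keep]),
                   resolution = config$contact_resolution, kind = "intra",
                   normalization_tag = "raw-synthetic",
                   genome = truth$genome[chrom])
  })
}

# Interactive bins of one chromosome: fixed across all pairs involving it.
.interactive_bins <- function(truth, config, chrom, bins_chrom) {
  fam <- .bin_true_family(bins_chrom, truth$isochores)
  rich <- which(fam %in% .GC_RICH)
  poor <- which(fam %in% .GC_POOR)
  n_rich <- round(config$interchrom_gcrich_preference * config$interchrom_hot_bins)
  n_poor <- config$interchrom_hot_bins - n_rich
  if (n_rich > length(rich) || n_poor > length(poor)) {
    warning("chromosome ", chrom, " has too few bins of one class; ",
            "interactive set truncated")
    n_rich <- min(n_rich, length(rich))
    n_poor <- min(n_poor, length(poor))
  }
  with_seed(stage_seed(config$seed, paste0("hot-", chrom)), {
    c(sample(rich, n_rich), sample(poor, n_poor))
  })
}

.simulate_inter <- function(truth, config, chroms) {
  bins <- make_bins(truth$genome[chroms], config$contact_resolution)
  ba <- bins[bins$chrom == chroms[1], ]
  bb <- bins[bins$chrom == chroms[2], ]
  hot_a <- ba$bin_id[.interactive_bins(truth, config, chroms[1], ba)]
  hot_b <- bb$bin_id[.interactive_bins(truth, config, chroms[2], bb)]
  with_seed(stage_seed(config$seed,
                       paste0("contacts-inter-", chroms[1], "-", chroms[2])), {
    i <- rep(ba$bin_id, times = nrow(bb))
    j <- rep(bb$bin_id, each = nrow(ba))
    mu <- rep(config$interchrom_base_mu, length(i))
    hi <- sample(hot_a, config$interchrom_hot_pairs, replace = TRUE)
    hj <- sample(hot_b, config$interchrom_hot_pairs, replace = TRUE)
    key <- (hi - 1) * nrow(bins) + hj
    add <- tapply(rep(config$interchrom_hot_mu, length(key)), key, sum)
    kidx <- match(as.numeric(names(add)), (i - 1) * nrow(bins) + j)
    mu[kidx] <- mu[kidx] + as.numeric(add)
    v <- stats::rpois(length(mu), mu)
    keep <- v > 0
    contact_matrix(bins,
                   data.frame(bin_i = i[keep], bin_j = j[keep],
                              value = v[keep]),
                   resolution = config$contact_resolution, kind = "inter",
                   normalization_tag = "raw-synthetic",
                   genome = truth$genome[chroms])
  })
}
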