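#' Simulation configuration for synthetic isochore genomes
#'
#' Bundles every knob of the synthetic-data generator: the isochore
#' mosaic (family GC targets, lognormal length laws, Markov family
#' succession), the within-isochore GC noise, the domain generator
#' (TAD boundary jitter, discordant fraction, LAD lamina contact
#' frequency Beta laws), the contact-matrix generator (power-law
#' distance decay, domain block boost, GC-poor long-range boost,
#' inter-chromosomal GC-rich preference) and the ortholog/CTCF
#' generators.
#'
#' Default scales emulate the mammalian situation: isochore median
#' lengths fall in the 0.2--2 Mb range of chromatin domains, with the
#' GC-poorest (LAD-forming) families skewed larger; contact matrices are
#' binned at 250 kb; the inter-chromosomal GC-rich preference defaults
#' to 0.75, the class split reported for top inter-chromosomal
#' interactions in real Hi-C data.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_chromosomes Number of chromosomes to simulate.
#' @param chromosome_length Length of each chromosome in bp.
#' @param family_gc_targets Named numeric, target GC% per family,
#'   strictly increasing from L1 to H3.
#' @param family_length_params Matrix with rows per family and columns
#'   `meanlog`, `sdlog`: the lognormal isochore length law (bp).
#' @param family_transition 5x5 row-stochastic matrix of family
#'   succession probabilities; zero diagonal so adjacent isochores always
#'   differ in family.
#' @param min_isochore_length Lower truncation (bp) for drawn isochore
#'   lengths.
#' @param noise_window Window (bp) at which GC noise is applied during
#'   sequence generation.
#' @param window_noise_sd SD (GC%) of the Gaussian per-window GC noise.
#' @param tad_jitter_sd SD (bp) of the Gaussian jitter applied to TAD
#'   endpoints.
#' @param discordant_tad_fraction Fraction of TADs placed uniformly at
#'   random instead of on an isochore.
#' @param lad_cf_params Named list, per GC-poor family, of `c(alpha, beta)`
#'   Beta parameters for the nuclear-lamina contact frequency (CF, the
#'   proportion of cells in which the segment touches the lamina).
#' @param contact_resolution Contact-matrix bin size in bp.
#' @param decay_exponent Power-law exponent of contact decay with
#'   distance.
#' @param contact_base Expected contact count at one bin distance.
#' @param domain_boost Multiplicative boost for bin pairs inside the same
#'   true isochore (the TAD block signal).
#' @param gcpoor_longrange_boost Multiplicative boost for bin pairs that
#'   are both GC-poor (L1/L2), producing the far-from-diagonal GC-poor
#'   interaction signal.
#' @param interchrom_gcrich_preference Proportion in `[0, 1]` of
#'   interaction-prone ("interactive") bins per chromosome drawn from the
#'   GC-rich class.
#' @param interchrom_hot_bins Number of interactive bins per chromosome.
#' @param interchrom_hot_pairs Number of hotspot bin pairs per chromosome
#'   pair.
#' @param interchrom_hot_mu Added Poisson mean per hotspot pair.
#' @param interchrom_base_mu Background Poisson mean for inter-chromosomal
#'   bin pairs.
#' @param ortholog_gc_noise_sd SD (GC%) of the species-B GC deviation
#'   from species A.
#' @param genes_per_block Number of consecutive orthologs per planted
#'   synteny block (must be >= 3 to be detectable).
#' @param gene_spacing Spacing (bp) between consecutive gene starts on
#'   species A.
#' @param ctcf_density Named numeric, CTCF sites per Mb per family;
#'   default is a strictly increasing gradient from L1 to H3.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 1, chromosome_length = 5e6)
#' cfg$family_gc_targets
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 2e7,
                       family_gc_targets = c(L1 = 35, L2 = 39, H1 = 43.5,
                                             H2 = 49.5, H3 = 55),
                       family_length_params = default_length_params(),
                       family_transition = default_family_transition(),
                       min_isochore_length = 2.5e5,
                       noise_window = 1e5,
                       window_noise_sd = 1.0,
                       tad_jitter_sd = 5e4,
                       discordant_tad_fraction = 0,
                       lad_cf_params = list(L1 = c(alpha = 8, beta = 2),
                                            L2 = c(alpha = 4, beta = 4)),
                       contact_resolution = 2.5e5,
                       decay_exponent = 1.0,
                       contact_base = 50,
                       domain_boost = 4,
                       gcpoor_longrange_boost = 3,
                       interchrom_gcrich_preference = 0.75,
                       interchrom_hot_bins = 24L,
                       interchrom_hot_pairs = 150L,
                       interchrom_hot_mu = 30,
                       interchrom_base_mu = 1,
                       ortholog_gc_noise_sd = 2,
                       genes_per_block = 5L,
                       gene_spacing = 4e5,
                       ctcf_density = c(L1 = 2, L2 = 5, H1 = 8,
                                        H2 = 11, H3 = 14)) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length,
              family_gc_targets = family_gc_targets,
              family_length_params = family_length_params,
              family_transition = family_transition,
              min_isochore_length = min_isochore_length,
              noise_window = noise_window,
              window_noise_sd = window_noise_sd,
              tad_jitter_sd = tad_jitter_sd,
              discordant_tad_fraction = discordant_tad_fraction,
              lad_cf_params = lad_cf_params,
              contact_resolution = contact_resolution,
              decay_exponent = decay_exponent,
              contact_base = contact_base,
              domain_boost = domain_boost,
              gcpoor_longrange_boost = gcpoor_longrange_boost,
              interchrom_gcrich_preference = interchrom_gcrich_preference,
              interchrom_hot_bins = as.integer(interchrom_hot_bins),
              interchrom_hot_pairs = as.integer(interchrom_hot_pairs),
              interchrom_hot_mu = interchrom_hot_mu,
              interchrom_base_mu = interchrom_base_mu,
              ortholog_gc_noise_sd = ortholog_gc_noise_sd,
              genes_per_block = as.integer(genes_per_block),
              gene_spacing = gene_spacing,
              ctcf_density = ctcf_density)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default lognormal isochore length parameters
#'
#' Median lengths per family (1.2 Mb down to 0.4 Mb from L1 to H3) fall
#' inside the 0.2--2 Mb chromatin-domain range, with GC-poor
#' (LAD-forming) isochores skewed larger than GC-rich ones.
#'
#' @return Matrix with rownames L1..H3 and columns `meanlog`, `sdlog`.
#' @export
default_length_params <- function() {
  med <- c(L1 = 1.2e6, L2 = 8e5, H1 = 6e5, H2 = 5e5, H3 = 4e5)
  cbind(meanlog = log(med), sdlog = rep(0.4, 5))
}

#' Default isochore family transition matrix
#'
#' Uniform over the four other families (zero diagonal, so adjacent
#' isochores always belong to distinct families); its stationary
#' distribution is uniform.
#'
#' @return A 5x5 row-stochastic matrix with family dimnames.
#' @export
default_family_transition <- function() {
  p <- matrix(0.25, 5, 5, dimnames = list(.FAMILIES, .FAMILIES))
  diag(p) <- 0
  p
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1L,
            cfg$chromosome_length > 0,
            cfg$min_isochore_length > 0,
            cfg$noise_window > 0,
            cfg$window_noise_sd >= 0,
            cfg$tad_jitter_sd >= 0,
            cfg$contact_resolution > 0,
            cfg$gene_spacing > 0)
  if (cfg$chromosome_length < cfg$min_isochore_length)
    stop("chromosome_length is smaller than one minimal isochore")
  tg <- cfg$family_gc_targets
  if (!identical(names(tg), .FAMILIES) || any(diff(tg) <= 0))
    stop("family_gc_targets must be named L1..H3 and strictly increasing")
  lp <- cfg$family_length_params
  if (!is.matrix(lp) || nrow(lp) != 5L ||
      !all(c("meanlog", "sdlog") %in% colnames(lp)))
    stop("family_length_params must be a 5-row matrix with meanlog and sdlog")
  tr <- cfg$family_transition
  if (!is.matrix(tr) || any(dim(tr) != 5L))
    stop("family_transition must be a 5x5 matrix")
  if (any(abs(rowSums(tr) - 1) > 1e-8))
    stop("family_transition rows must sum to 1")
  if (any(diag(tr) != 0))
    stop("family_transition must have a zero diagonal (adjacent isochores ",
         "must differ in family)")
  if (any(tr < 0)) stop("family_transition entries must be non-negative")
  for (p in c("discordant_tad_fraction", "interchrom_gcrich_preference"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  if (any(cfg$ctcf_density < 0)) stop("ctcf_density rates must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_chromosomes, "chromosome(s) of",
      format(x$chromosome_length, big.mark = ","), "bp\n")
  cat("  GC targets:", paste(names(x$family_gc_targets),
                             x$family_gc_targets, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
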