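# The synthetic-genome generator: determinism, tiling, planted GC,
# domain and CTCF laws.

test_that("isochore structure tiles chromosomes with distinct adjacent families", {
  for (seed in 1:5) {
    tr <- simulate_isochore_structure(quick_config(seed, n_chromosomes = 2))
    for (chrom in names(tr$genome)) {
      iso <- tr$isochores[tr$isochores$chrom == chrom, ]
      expect_equal(iso$start[1], 0)
      expect_equal(iso$end[nrow(iso)], unname(tr$genome[[chrom]]))
      if (nrow(iso) > 1) {
        expect_equal(iso$start[-1], iso$end[-nrow(iso)])
        expect_true(all(iso$family[-1] != iso$family[-nrow(iso)]))
      }
      expect_true(all(iso$end - iso$start >=
                        tr$config$min_isochore_length - 1))
    }
  }
})

test_that("identical configs give byte-identical sequence and truth", {
  cfg <- quick_config(11, chromosome_length = 1e6)
  g1 <- simulate_isochore_genome(cfg)
  g2 <- simulate_isochore_genome(cfg)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$truth$isochores, g2$truth$isochores)
  # and the seed really drives the draw
  g3 <- simulate_isochore_genome(quick_config(12, chromosome_length = 1e6))
  expect_false(identical(as.character(g1$sequences),
                         as.character(g3$sequences)))
})

test_that("a noise-free constant-GC genome has the target GC in every window", {
  # pinning all five targets to ~55% GC with zero window noise makes
  # every 100 kb window a pure binomial draw around 55%
  cfg <- sim_config(seed = 21, n_chromosomes = 1, chromosome_length = 1e6,
                    window_noise_sd = 0,
                    family_gc_targets = c(L1 = 54.96, L2 = 54.98, H1 = 55,
                                          H2 = 55.02, H3 = 55.04))
  g <- simulate_isochore_genome(cfg)
  prof <- compute_gc_profile(g$sequences[[1]], window = 1e5)
  # binomial sampling error at n = 1e5 per window: sd ~ 0.16 GC%
  expect_true(all(abs(prof$gc - 55) < 1))
})

test_that("family composition follows the stationary law of the transition matrix", {
  # biased transition matrix with a non-uniform stationary distribution
  p <- matrix(c(0, .4, .3, .2, .1,
                .5, 0, .3, .1, .1,
                .4, .3, 0, .2, .1,
                .3, .3, .2, 0, .2,
                .2, .2, .3, .3, 0), 5, 5, byrow = TRUE,
              dimnames = list(isochore_families(), isochore_families()))
  # oracle: solve the stationary equations directly
  A <- rbind(t(p) - diag(5), rep(1, 5))
  pi_oracle <- qr.solve(A, c(rep(0, 5), 1))
  expect_equal(unname(transition_stationary(p)), unname(pi_oracle),
               tolerance = 1e-8)
  counts <- integer(5)
  for (seed in 1:50) {
    tr <- simulate_isochore_structure(
      sim_config(seed = seed, n_chromosomes = 1, chromosome_length = 2e7,
                 family_transition = p))
    counts <- counts + as.integer(table(factor(tr$isochores$family,
                                               isochore_families())))
  }
  frac <- counts / sum(counts)
  # multinomial error over ~1000 isochores: 3 sigma ~ 0.04
  expect_true(all(abs(frac - pi_oracle) < 0.05))
})

test_that("per-family mean GC of generated sequence is close to the target", {
  g <- simulate_isochore_genome(sim_config(seed = 31, n_chromosomes = 1,
                                           chromosome_length = 1e7))
  iso <- g$truth$isochores
  seq1 <- g$sequences[[1]]
  big <- which(iso$end - iso$start >= 5e5)
  for (k in big) {
    f <- Biostrings::letterFrequency(
      Biostrings::subseq(seq1, iso$start[k] + 1, iso$end[k]),
      c("A", "C", "G", "T"))
    gc <- 100 * (f[["C"]] + f[["G"]]) / sum(f)
    expect_lt(abs(gc - iso$gc[k]), 1)
  }
})

test_that("zero jitter and no discordance reproduce the isochores as TADs", {
  cfg <- quick_config(41, tad_jitter_sd = 0, discordant_tad_fraction = 0)
  tr <- simulate_isochore_structure(cfg)
  d <- simulate_domains(tr, cfg)
  expect_equal(d$tads$start, tr$isochores$start)
  expect_equal(d$tads$end, tr$isochores$end)
  expect_true(all(d$tads$source != "discordant"))
})

test_that("discordant fraction one labels every TAD discordant", {
  cfg <- quick_config(42, discordant_tad_fraction = 1)
  tr <- simulate_isochore_structure(cfg)
  d <- simulate_domains(tr, cfg)
  expect_true(all(d$tads$source == "discordant"))
  expect_true(all(is.na(d$tads$source_family)))
})

test_that("LADs are the GC-poor isochores and L1 contact frequencies dominate L2", {
  wins <- 0L
  for (seed in 1:100) {
    cfg <- quick_config(seed, chromosome_length = 2e7)
    tr <- simulate_isochore_structure(cfg)
    d <- simulate_domains(tr, cfg)
    expect_true(all(d$lads$family %in% c("L1", "L2")))
    expect_true(all(d$lads$cf >= 0 & d$lads$cf <= 1))
    m1 <- mean(d$lads$cf[d$lads$family == "L1"])
    m2 <- mean(d$lads$cf[d$lads$family == "L2"])
    if (is.finite(m1) && is.finite(m2) && m1 > m2) wins <- wins + 1L
  }
  expect_gte(wins, 95)
})

test_that("contact matrices are symmetric with the planted distance decay", {
  cfg <- sim_config(seed = 51, n_chromosomes = 1, chromosome_length = 2e7,
                    domain_boost = 1, gcpoor_longrange_boost = 1)
  tr <- simulate_isochore_structure(cfg)
  m <- simulate_contact_matrix(tr, cfg, "intra")
  expect_true(all(m$values$bin_i <= m$values$bin_j))
  n <- nrow(m$bins)
  lookup <- function(i, j) {
    v <- m$values$value[m$values$bin_i == min(i, j) &
                          m$values$bin_j == max(i, j)]
    if (length(v)) v else 0
  }
  # decay_exponent = 1: mean contact at distance 2 ~ half of distance 1
  v1 <- mean(vapply(seq_len(n - 1), function(i) lookup(i, i + 1), numeric(1)))
  v2 <- mean(vapply(seq_len(n - 2), function(i) lookup(i, i + 2), numeric(1)))
  expect_lt(abs(v2 / v1 - 0.5), 0.1)
})

test_that("inter-chromosomal simulation needs two chromosomes", {
  cfg <- quick_config(61)
  tr <- simulate_isochore_structure(cfg)
  expect_error(simulate_contact_matrix(tr, cfg, "inter"),
               "at least 2 chromosomes")
})

test_that("unshuffled ortholog tables are collinear and noise-free GC matches", {
  cfg <- sim_config(seed = 71, n_chromosomes = 1, chromosome_length = 2e7,
                    ortholog_gc_noise_sd = 0)
  tr <- simulate_isochore_structure(cfg)
  orth <- simulate_orthologs(tr, cfg, shuffle = FALSE)
  expect_true(all(diff(orth$pairs$start_b) > 0))
  expect_true(all(orth$pairs$strand_b == "+"))
  expect_true(all(orth$blocks$orientation == "direct"))
  bl <- build_synteny_blocks(orth$pairs)
  oi <- orthologous_isochores(bl, tr$isochores, orth$b_regions)
  expect_gt(nrow(oi), 5)
  expect_equal(oi$gc_b, oi$gc_a, tolerance = 1e-9)
})

test_that("blocks of fewer than three genes are rejected at simulation time", {
  cfg <- quick_config(72)
  cfg$genes_per_block <- 2L
  tr <- simulate_isochore_structure(quick_config(72))
  expect_error(simulate_orthologs(tr, cfg), "genes_per_block")
})

test_that("CTCF sites follow the per-family Poisson law", {
  cfg <- quick_config(81)
  tr <- simulate_isochore_structure(cfg)
  zero <- simulate_ctcf_sites(tr, densities = c(L1 = 0, L2 = 0, H1 = 0,
                                                H2 = 0, H3 = 0))
  expect_equal(nrow(zero), 0)
  # single isochore at a known rate: counts ~ Poisson(10) over seeds
  tr1 <- tr
  tr1$isochores <- data.frame(chrom = "chr1", start = 0, end = 1e6,
                              family = "H3", gc = 55)
  counts <- vapply(1:200, function(s)
    nrow(simulate_ctcf_sites(tr1, densities = c(L1 = 0, L2 = 0, H1 = 0,
                                                H2 = 0, H3 = 10),
                             seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 10), 1)      # se = sqrt(10/200) ~ 0.22
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.35)
  expect_true(all(counts >= 0))
})
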