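# Overlap statistics, randomization schemes, permutation tests and
# local z-score profiles.

test_that("overlap statistic handles the elementary cases", {
  g <- c(chr1 = 1000)
  A <- region_set(data.frame(chrom = "chr1", start = 0, end = 100), g)
  B <- region_set(data.frame(chrom = "chr1", start = 50, end = 150), g)
  expect_equal(overlap_statistic(A, B, "count"), 1)
  expect_equal(overlap_statistic(A, B, "basepair"), 50)
  C <- region_set(data.frame(chrom = "chr1", start = 500, end = 600), g)
  expect_equal(overlap_statistic(A, C, "count"), 0)
  expect_equal(overlap_statistic(A, C, "basepair"), 0)
  # identity: count = |A|, basepair = union bp
  D <- region_set(data.frame(chrom = "chr1", start = c(0, 200, 300),
                             end = c(100, 250, 400)), g)
  expect_equal(overlap_statistic(D, D, "count"), 3)
  expect_equal(overlap_statistic(D, D, "basepair"), 250)
  g2 <- c(chr1 = 2000)
  E <- region_set(data.frame(chrom = "chr1", start = 0, end = 10), g2)
  expect_error(overlap_statistic(A, E), "different genomes")
})

test_that("overlap statistic matches the quadratic-scan oracle on fuzzed sets", {
  genome <- c(chr1 = 600, chr2 = 400)
  set.seed(404)
  for (rep in 1:40) {
    a <- random_regions(sample.int(50, 1), genome)
    b <- random_regions(sample.int(50, 1), genome)
    A <- region_set(a, genome); B <- region_set(b, genome)
    expect_equal(overlap_statistic(A, B, "count"),
                 brute_overlap(a, b, "count"))
    expect_equal(overlap_statistic(A, B, "basepair"),
                 brute_overlap(a, b, "basepair"))
    # symmetry of the basepair statistic
    expect_equal(overlap_statistic(A, B, "basepair"),
                 overlap_statistic(B, A, "basepair"))
  }
})

test_that("randomization preserves interval count and length multiset", {
  genome <- c(chr1 = 1e6, chr2 = 5e5)
  set.seed(7)
  df <- random_regions(30, genome, max_len = 1e4)
  rs <- region_set(df, genome)
  for (scheme in c("uniform", "circular")) {
    r <- randomize_regions(rs, scheme, seed = 99)
    expect_equal(length(unique(r$regions$id)), 30)
    # per-id total length is conserved even across circular wrapping
    len_in <- sort(df$end - df$start)
    len_out <- sort(as.numeric(tapply(r$regions$end - r$regions$start,
                                      r$regions$id, sum)))
    expect_equal(len_out, len_in)
    # chromosome assignment conserved
    expect_equal(sort(unique(paste(r$regions$chrom, r$regions$id))),
                 sort(unique(paste(df$chrom, seq_len(nrow(df))))))
    # bounds respected
    expect_true(all(r$regions$start >= 0 &
                      r$regions$end <= genome[r$regions$chrom]))
    # uniform placement never overlaps itself
    if (scheme == "uniform") {
      for (chrom in names(genome)) {
        d <- r$regions[r$regions$chrom == chrom, ]
        d <- d[order(d$start), ]
        if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
      }
    }
  }
})

test_that("a zero circular offset is the identity", {
  genome <- c(chr1 = 1e5)
  rs <- region_set(data.frame(chrom = "chr1", start = c(0, 5e4),
                              end = c(1e4, 6e4)), genome)
  r <- randomize_regions(rs, "circular", offset = 0)
  expect_equal(r$regions$start, c(0, 5e4))
  expect_equal(r$regions$end, c(1e4, 6e4))
})

test_that("uniform placement lands in the single feasible slot", {
  genome <- c(chr1 = 1000)
  # mask everything except [400, 450): only slot for a 50 bp interval
  mask <- data.frame(chrom = "chr1", start = c(0, 450), end = c(400, 1000))
  rs <- region_set(data.frame(chrom = "chr1", start = 0, end = 50),
                   genome, mask = mask)
  # degenerate RNG state is irrelevant: the slot is unique
  for (seed in 1:5) {
    r <- randomize_regions(rs, "uniform", seed = seed)
    expect_equal(r$regions$start, 400)
    expect_equal(r$regions$end, 450)
  }
  # no feasible slot at all: error naming the chromosome
  rs2 <- region_set(data.frame(chrom = "chr1", start = 0, end = 60),
                    genome, mask = mask)
  expect_error(randomize_regions(rs2, "uniform", seed = 1), "chr1")
})

test_that("self-association of a sparse set attains the minimum p-value", {
  genome <- c(chr1 = 1e7)
  set.seed(11)
  df <- random_regions(25, genome, max_len = 1.5e4)  # < 5% of the genome
  A <- region_set(df, genome)
  pt <- perm_test(A, A, n_perm = 199, mode = "basepair", seed = 3)
  expect_equal(pt$p_value, 1 / 200)
  expect_gt(pt$z_score, 5)
  # reproducibility: identical seeds give identical nulls
  pt2 <- perm_test(A, A, n_perm = 199, mode = "basepair", seed = 3)
  expect_identical(pt$null_values, pt2$null_values)
})

test_that("a whole-genome target saturates the test at p = 1", {
  genome <- c(chr1 = 1e6)
  A <- region_set(random_regions(10, genome), genome)
  B <- region_set(data.frame(chrom = "chr1", start = 0, end = 1e6), genome)
  pt <- perm_test(A, B, n_perm = 99, mode = "count", seed = 5)
  expect_equal(pt$p_value, 1)
  expect_true(is.na(pt$z_score))  # degenerate null flagged
})

test_that("null z-scores are approximately standard normal", {
  genome <- c(chr1 = 5e6)
  set.seed(21)
  A <- region_set(random_regions(40, genome, max_len = 5e4), genome)
  B <- region_set(random_regions(40, genome, max_len = 5e4), genome)
  pt <- perm_test(A, B, n_perm = 1000, mode = "basepair", seed = 9)
  z <- (pt$null_values - pt$null_mean) / pt$null_sd
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("the local z profile is anchored at the permutation z-score", {
  genome <- c(chr1 = 2e6)
  set.seed(31)
  A <- region_set(random_regions(20, genome, max_len = 3e4), genome)
  lz <- local_z_profile(A, A, max_shift = 2e5, step = 5e4, n_perm = 99,
                        mode = "basepair", seed = 17)
  expect_true(0 %in% lz$profile$shift)
  expect_equal(sort(lz$profile$shift), sort(-lz$profile$shift))
  expect_equal(lz$profile$z[lz$profile$shift == 0], lz$shift0$z_score)
  pt <- perm_test(A, A, n_perm = 99, mode = "basepair", seed = 17)
  expect_equal(lz$shift0$z_score, pt$z_score)
  expect_error(local_z_profile(A, A, max_shift = 2e5, step = 3e4,
                               n_perm = 9, seed = 1),
               "divide")
})

test_that("profile classification separates constant from peaked profiles", {
  flat <- structure(list(profile = data.frame(shift = -2:2 * 1e5,
                                              z = rep(8, 5)),
                         peak_sharpness = 1),
                    class = "local_z_profile")
  expect_equal(classify_profile(flat), "flat")
  sharp <- structure(list(profile = data.frame(shift = -2:2 * 1e5,
                                               z = c(5, 10, 30, 10, 5)),
                          peak_sharpness = 6),
                     class = "local_z_profile")
  expect_equal(classify_profile(sharp), "sharp")
})
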