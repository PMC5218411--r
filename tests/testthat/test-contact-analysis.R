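# Bin annotation, stratified contact statistics, top interactions,
# boundary concordance and LAD contact-frequency summaries.

mk_bins <- function(n, chrom = "chr1", res = 100) {
  data.frame(bin_id = seq_len(n), chrom = chrom,
             start = (seq_len(n) - 1) * res, end = seq_len(n) * res)
}

test_that("contact matrices canonicalise and validate their entries", {
  bins <- mk_bins(4)
  m <- contact_matrix(bins, data.frame(bin_i = c(2, 1), bin_j = c(1, 3),
                                       value = c(5, 2)),
                      resolution = 100, kind = "intra")
  expect_equal(m$values$bin_i, c(1, 1))
  expect_equal(m$values$bin_j, c(2, 3))
  # symmetric duplicates are accepted, contradictions are not
  ok <- contact_matrix(bins, data.frame(bin_i = c(1, 2), bin_j = c(2, 1),
                                        value = c(5, 5)),
                       resolution = 100, kind = "intra")
  expect_equal(nrow(ok$values), 1)
  expect_error(contact_matrix(bins,
                              data.frame(bin_i = c(1, 2), bin_j = c(2, 1),
                                         value = c(5, 6)),
                              resolution = 100, kind = "intra"),
               "asymmetric")
  expect_error(contact_matrix(bins,
                              data.frame(bin_i = 1, bin_j = 2, value = -1),
                              resolution = 100, kind = "intra"),
               "non-negative")
  bad_bins <- bins
  bad_bins$start[2] <- 150
  expect_error(contact_matrix(bad_bins,
                              data.frame(bin_i = 1, bin_j = 2, value = 1),
                              resolution = 100, kind = "intra"),
               "tiling")
})

test_that("bin annotation follows majority overlap with midpoint tie-break", {
  bins <- mk_bins(3)
  iso <- data.frame(chrom = "chr1",
                    start = c(0, 100, 160, 250), end = c(100, 160, 250, 300),
                    family = c("H3", "L1", "H1", "L2"))
  ann <- annotate_bins(bins, iso)
  # bin 2 is 60% L1 / 40% H1: majority rule; bin 3 is an exact 50/50
  # tie between H1 and L2 with the midpoint (250) in the L2 isochore
  expect_equal(ann$family, c("H3", "L1", "L2"))
  expect_equal(ann$class, c("GC-rich", "GC-poor", "GC-poor"))
  # exact 50/50 tie: midpoint at 150 sits in the right-hand isochore
  iso2 <- data.frame(chrom = "chr1", start = c(100, 150), end = c(150, 200),
                     family = c("L1", "H2"))
  ann2 <- annotate_bins(mk_bins(3), iso2)
  expect_equal(ann2$family[2], "H2")
  # a bin covered on less than half its length stays unassigned
  expect_equal(ann2$family[3], "unassigned")
  expect_equal(ann2$class[3], "unassigned")
})

test_that("stratified profile means are exact on a constant matrix", {
  n <- 10
  bins <- mk_bins(n)
  pairs <- t(combn(n, 2))
  m <- contact_matrix(bins, data.frame(bin_i = pairs[, 1],
                                       bin_j = pairs[, 2], value = 7),
                      resolution = 100, kind = "intra")
  iso <- data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 1000),
                    family = c("L1", "H3"))
  ann <- annotate_bins(bins, iso)
  prof <- stratified_contact_profile(m, ann, distance_breaks = c(300, 600))
  expect_true(all(prof$mean_value == 7))
  # unordered class pairs: every cell appears once
  expect_equal(anyDuplicated(prof[c("class_i", "class_j", "stratum")]), 0)
  expect_true(all(prof$class_i <= prof$class_j))
  # conservation: every annotated pair counted exactly once
  expect_equal(sum(prof$n_pairs), choose(n, 2))
  # absent sparse entries count as zeros
  m2 <- contact_matrix(bins, data.frame(bin_i = 1, bin_j = 2, value = 7),
                       resolution = 100, kind = "intra")
  prof2 <- stratified_contact_profile(m2, ann, distance_breaks = c(300, 600))
  expect_equal(sum(prof2$n_pairs * prof2$mean_value), 7)
})

test_that("top interactions order by value with lexicographic tie-break", {
  bins <- rbind(mk_bins(3),
                data.frame(bin_id = 4:7, chrom = "chr2",
                           start = 0:3 * 100, end = 1:4 * 100))
  vals <- expand.grid(bin_i = 1:3, bin_j = 4:7)
  vals$value <- c(12, 1, 5, 3, 8, 2, 9, 4, 6, 7, 10, 11)
  m <- contact_matrix(bins, vals, resolution = 100, kind = "inter")
  top2 <- top_interactions(m, 2)
  expect_equal(top2$value, c(12, 11))
  # ties: ascending (bin_i, bin_j)
  vals$value <- 5
  m2 <- contact_matrix(bins, vals, resolution = 100, kind = "inter")
  t2 <- top_interactions(m2, 2)
  expect_equal(t2$bin_i, c(1, 1))
  expect_equal(t2$bin_j, c(4, 5))
  # saturation: fewer non-zero entries than requested
  m3 <- contact_matrix(bins, data.frame(bin_i = 1:2, bin_j = c(4, 5),
                                        value = c(3, 1)),
                       resolution = 100, kind = "inter")
  expect_warning(t3 <- top_interactions(m3, 10), "non-zero")
  expect_equal(nrow(t3), 2)
  # intra matrices are refused
  mi <- contact_matrix(mk_bins(3), data.frame(bin_i = 1, bin_j = 2,
                                              value = 1),
                       resolution = 100, kind = "intra")
  expect_error(top_interactions(mi, 1), "inter")
})

test_that("class fractions count distinct bins and sum to one", {
  ann <- data.frame(bin_id = 1:4, chrom = c("chr1", "chr1", "chr2", "chr2"),
                    start = c(0, 100, 0, 100), end = c(100, 200, 100, 200),
                    family = c("H3", "H1", "L1", "unassigned"),
                    class = c("GC-rich", "GC-rich", "GC-poor", "unassigned"))
  tops <- data.frame(chrom_i = "chr1", start_i = c(0, 0, 100),
                     chrom_j = "chr2", start_j = c(0, 0, 0))
  f <- interaction_class_fractions(tops, ann)
  expect_equal(f$n_bins, 3)  # chr1:0 counted once
  expect_equal(f$frac_gc_rich + f$frac_gc_poor, 1)
  expect_equal(f$frac_gc_rich, 2 / 3)
  all_rich <- interaction_class_fractions(
    data.frame(chrom_i = "chr1", start_i = 0, chrom_j = "chr1",
               start_j = 100), ann)
  expect_equal(all_rich$frac_gc_rich, 1)
  expect_equal(all_rich$frac_gc_poor, 0)
})

test_that("boundary concordance handles identity and missing isochores", {
  iso <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6),
                    family = c("L1", "H1"))
  expect_equal(boundary_concordance(iso, iso, tolerance = 0)$fraction, 1)
  far <- data.frame(chrom = "chr2", start = 0, end = 1e6)
  expect_equal(boundary_concordance(far, iso, tolerance = 1e5)$fraction, 0)
  near <- data.frame(chrom = "chr1", start = 4e4, end = 1.2e6)
  cc <- boundary_concordance(near, iso, tolerance = 1e5)
  expect_equal(cc$n_matched, 1)  # start within 40 kb of 0; end 200 kb off
  expect_equal(cc$n_total, 2)
})

test_that("LAD contact frequencies summarise per assigned family", {
  iso <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6),
                    family = c("L1", "L2"))
  empty <- lad_cf_by_family(data.frame(chrom = character(0),
                                       start = numeric(0), end = numeric(0),
                                       cf = numeric(0)), iso)
  expect_equal(nrow(empty), 0)
  lads <- data.frame(chrom = "chr1", start = c(0, 2e5, 1.1e6),
                     end = c(1e5, 4e5, 1.6e6), cf = c(1, 0.9, 0.3))
  tab <- lad_cf_by_family(lads, iso)
  expect_equal(tab$family, c("L1", "L2"))
  expect_equal(tab$n, c(2, 1))
  expect_equal(tab$mean_cf, c(0.95, 0.3))
  expect_equal(tab$frac_high_cf, c(1, 0))
  expect_error(lad_cf_by_family(data.frame(chrom = "chr1", start = 0,
                                           end = 10, cf = 1.5), iso),
               "\\[0, 1\\]")
})

test_that("contact matrices round-trip through bin and triplet files", {
  cfg <- sim_config(seed = 91, n_chromosomes = 1, chromosome_length = 5e6)
  tr <- simulate_isochore_structure(cfg)
  m <- simulate_contact_matrix(tr, cfg, "intra")
  bp <- tempfile(fileext = ".tsv"); tp <- tempfile(fileext = ".tsv")
  write_contact_matrix(m, bp, tp)
  m2 <- read_contact_matrix(bp, tp, resolution = cfg$contact_resolution,
                            kind = "intra")
  expect_equal(m2$values, m$values)
  expect_equal(m2$bins$start, m$bins$start)
})
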