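# End-to-end orchestration: simulate -> profile -> segment -> associate
# -> synteny -> contacts -> report.

#' Pipeline configuration
#'
#' Bundles the simulation config with the analysis parameters of every
#' stage. One global seed deterministically derives all stage seeds via
#' [stage_seed()].
#'
#' @param sim A [sim_config()]; its seed is replaced by `seed`.
#' @param seed Global seed.
#' @param window,step GC profile window/step in bp.
#' @param min_size Minimum isochore size for segmentation (bp).
#' @param boundaries A [family_boundaries()].
#' @param n_perm Permutations for association tests.
#' @param assoc_mode,assoc_scheme Overlap statistic mode and
#'   randomization scheme.
#' @param max_shift,shift_step Local z-score profile range/step (bp).
#' @param min_genes Minimum orthologs per synteny block.
#' @param distance_breaks Distance strata (bp) for contact profiles.
#' @param top_n Top interactions per chromosome pair.
#' @param tolerance Boundary concordance tolerance (bp).
#' @param cf_threshold High lamina-contact-frequency threshold.
#' @param write_fasta Write the simulated genome FASTA (the slowest
#'   output; disable for structure-only runs).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1L,
                            window = 1e5, step = window, min_size = 2e5,
                            boundaries = family_boundaries("fixed"),
                            n_perm = 199L, assoc_mode = "basepair",
                            assoc_scheme = "uniform",
                            max_shift = 3e6, shift_step = 2.5e5,
                            min_genes = 3L,
                            distance_breaks = c(1e6, 2.5e6, 5e6, 1e7),
                            top_n = 100L, tolerance = 1e5,
                            cf_threshold = 0.8, write_fasta = TRUE) {
  sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  structure(list(sim = sim, seed = as.integer(seed), window = window,
                 step = step, min_size = min_size, boundaries = boundaries,
                 n_perm = as.integer(n_perm), assoc_mode = assoc_mode,
                 assoc_scheme = assoc_scheme, max_shift = max_shift,
                 shift_step = shift_step, min_genes = as.integer(min_genes),
                 distance_breaks = distance_breaks,
                 top_n = as.integer(top_n), tolerance = tolerance,
                 cf_threshold = cf_threshold, write_fasta = write_fasta),
            class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in dependency order: genome simulation, GC profiling and
#' isochore segmentation, TAD/LAD simulation, permutation association
#' tests (TADs not overlapping LADs versus GC-rich isochores; LADs
#' versus GC-poor isochores, both in basepair mode since isochores tile
#' the genome), the local z-score profile of the TAD test, synteny-block
#' construction and cross-species GC correlation, contact-matrix
#' stratification, boundary concordance, CTCF density and LAD CF
#' summaries. Every intermediate is written under `out_dir` in the
#' declared plain-text formats, a `MANIFEST` records stage completion,
#' and the machine-readable `report.json` is written last. Reports are
#' regenerable bit-identically from the same config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return The report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(out_dir, "MANIFEST")
  done <- character(0)
  note <- function(stage) {
    done <<- c(done, stage)
    writeLines(done, manifest)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list(package = "isoarch",
                 version = as.character(utils::packageVersion("isoarch")),
                 seed = config$seed)

  # -- simulate ---------------------------------------------------------
  sim <- config$sim
  gen <- run_stage("simulate", {
    if (config$write_fasta) simulate_isochore_genome(sim)
    else list(sequences = NULL, truth = simulate_isochore_structure(sim))
  })
  truth <- gen$truth
  write_genome(truth$genome, file.path(out_dir, "genome.tsv"))
  write_isochore_bed(truth$isochores, file.path(out_dir, "true_isochores.bed"))
  if (!is.null(gen$sequences))
    write_genome_fasta(gen$sequences, file.path(out_dir, "genome.fa"))
  note("simulate")

  # -- profile & segment ------------------------------------------------
  isochores <- run_stage("segment", {
    if (is.null(gen$sequences)) {
      truth$isochores
    } else {
      segs <- lapply(names(gen$sequences), function(chrom) {
        prof <- compute_gc_profile(gen$sequences[chrom], config$window,
                                   config$step)
        write_gc_profile(prof, file.path(out_dir,
                                         paste0("profile_", chrom, ".tsv")))
        segment_isochores(prof, config$boundaries, config$min_size)
      })
      do.call(rbind, segs)
    }
  })
  write_isochore_bed(isochores, file.path(out_dir, "isochores.bed"))
  if (!is.null(gen$sequences)) {
    acc <- segmentation_accuracy(isochores, truth$isochores, truth$genome,
                                 tolerance = config$window)
    report$segmentation <- acc
  }
  note("segment")

  # -- domains ----------------------------------------------------------
  domains <- run_stage("domains", simulate_domains(truth, sim))
  write_bed(domains$tads, file.path(out_dir, "tads.bed"),
            name_col = "source")
  lads_out <- domains$lads
  lads_out$cf_pct <- round(100 * lads_out$cf)
  write_bed(lads_out, file.path(out_dir, "lads.bed"),
            name_col = "family", score_col = "cf_pct")
  note("domains")

  # -- association ------------------------------------------------------
  assoc <- run_stage("association", {
    # TADs here follow the convention of excluding LAD-overlapping
    # domains, so the TAD test contrasts GC-rich structures.
    lad_red <- domains$lads
    keep <- vapply(seq_len(nrow(domains$tads)), function(k) {
      t <- domains$tads[k, ]
      l <- lad_red[lad_red$chrom == t$chrom, ]
      if (!nrow(l)) return(TRUE)
      ov <- pmax(0, pmin(l$end, t$end) - pmax(l$start, t$start))
      sum(ov) <= 0.5 * (t$end - t$start)
    }, logical(1))
    tad_rs <- region_set(domains$tads[keep, c("chrom", "start", "end")],
                         truth$genome, name = "TADs")
    rich_iso <- isochores[isochores$family %in% .GC_RICH,
                          c("chrom", "start", "end")]
    poor_iso <- isochores[isochores$family %in% .GC_POOR,
                          c("chrom", "start", "end")]
    rich_rs <- region_set(rich_iso, truth$genome, name = "GC-rich isochores")
    poor_rs <- region_set(poor_iso, truth$genome, name = "GC-poor isochores")
    lad_rs <- region_set(domains$lads[, c("chrom", "start", "end")],
                         truth$genome, name = "LADs")
    tad_test <- perm_test(tad_rs, rich_rs, n_perm = config$n_perm,
                          mode = config$assoc_mode,
                          scheme = config$assoc_scheme,
                          seed = stage_seed(config$seed, "assoc-tad"))
    lad_test <- perm_test(lad_rs, poor_rs, n_perm = config$n_perm,
                          mode = config$assoc_mode,
                          scheme = config$assoc_scheme,
                          seed = stage_seed(config$seed, "assoc-lad"))
    lz <- local_z_profile(tad_rs, rich_rs, max_shift = config$max_shift,
                          step = config$shift_step, n_perm = config$n_perm,
                          mode = config$assoc_mode,
                          scheme = config$assoc_scheme,
                          seed = stage_seed(config$seed, "localz"))
    utils::write.table(lz$profile, file.path(out_dir, "local_z.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(tad = tad_test, lad = lad_test, localz = lz)
  })
  report$association <- list(
    tad = list(observed = assoc$tad$observed, z = assoc$tad$z_score,
               p = assoc$tad$p_value, n_perm = assoc$tad$n_perm),
    lad = list(observed = assoc$lad$observed, z = assoc$lad$z_score,
               p = assoc$lad$p_value, n_perm = assoc$lad$n_perm),
    localz = list(peak_sharpness = assoc$localz$peak_sharpness,
                  classification = classify_profile(assoc$localz)))
  note("association")

  # -- synteny ----------------------------------------------------------
  syn <- run_stage("synteny", {
    orth <- simulate_orthologs(truth, sim)
    write_orthologs(orth$pairs, file.path(out_dir, "orthologs.tsv"))
    blocks <- build_synteny_blocks(orth$pairs, min_genes = config$min_genes)
    utils::write.table(blocks[, setdiff(names(blocks), "genes")],
                       file.path(out_dir, "synteny_blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pairs <- orthologous_isochores(blocks, truth$isochores, orth$b_regions)
    utils::write.table(pairs, file.path(out_dir, "orthologous_isochores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(stats = block_stats(blocks), cor = gc_correlation(pairs),
         n_planted = nrow(orth$blocks))
  })
  report$synteny <- list(n_blocks = syn$stats$count,
                         n_planted = syn$n_planted,
                         mean_span_bp = syn$stats$mean_span,
                         min_span_bp = syn$stats$min_span,
                         max_span_bp = syn$stats$max_span,
                         gc_pearson_r = syn$cor$pearson_r,
                         gc_spearman_rho = syn$cor$spearman_rho,
                         n_pairs = syn$cor$n)
  note("synteny")

  # -- contacts ---------------------------------------------------------
  contacts <- run_stage("contacts", {
    mat <- simulate_contact_matrix(truth, sim, kind = "intra",
                                   chroms = names(truth$genome)[1])
    write_contact_matrix(mat, file.path(out_dir, "intra_bins.tsv"),
                         file.path(out_dir, "intra_triplets.tsv"))
    ann <- annotate_bins(mat, truth$isochores)
    prof <- stratified_contact_profile(mat, ann, config$distance_breaks)
    utils::write.table(prof, file.path(out_dir, "contact_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- list(longrange_ratio = gcpoor_longrange_ratio(mat, ann))
    if (length(truth$genome) >= 2) {
      pairs <- utils::combn(names(truth$genome), 2)
      tops <- list(); anns <- list()
      for (k in seq_len(ncol(pairs))) {
        m <- simulate_contact_matrix(truth, sim, kind = "inter",
                                     chroms = pairs[, k])
        tops[[k]] <- top_interactions(m, config$top_n)
      }
      gw_bins <- make_bins(truth$genome, sim$contact_resolution)
      gw_ann <- annotate_bins(gw_bins, truth$isochores)
      out$class_fractions <-
        interaction_class_fractions(do.call(rbind, tops), gw_ann)
    }
    out
  })
  report$contacts <- list(
    gcpoor_longrange_ratio = contacts$longrange_ratio,
    interchrom = contacts$class_fractions)
  note("contacts")

  # -- concordance, CTCF, LAD CF ---------------------------------------
  extras <- run_stage("summaries", {
    conc <- boundary_concordance(domains$tads, truth$isochores,
                                 config$tolerance)
    ctcf <- simulate_ctcf_sites(truth)
    dens <- ctcf_density_by_family(ctcf, truth$isochores)
    ladcf <- lad_cf_by_family(domains$lads, truth$isochores,
                              config$cf_threshold)
    utils::write.table(dens, file.path(out_dir, "ctcf_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(conc = conc, dens = dens, ladcf = ladcf)
  })
  dd <- extras$dens[extras$dens$family %in% .FAMILIES, ]
  report$concordance <- extras$conc
  report$ctcf <- list(density_per_mb = stats::setNames(
    as.list(dd$density_per_mb), dd$family))
  report$lad_cf <- extras$ladcf
  note("summaries")

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("report")
  invisible(report)
}

#' Validate analysis input tables
#'
#' Checks interval tables for bounds and sortedness, ortholog tables for
#' one-to-one gene mapping, and contact triplet tables for symmetry
#' consistency. Returns a data frame of findings classified as
#' `"warning"` (auto-fixable, e.g. unsorted intervals) or `"fatal"`
#' (e.g. coordinates beyond the chromosome, asymmetric matrix entries).
#'
#' @param genome Named vector of chromosome lengths.
#' @param regions Named list of interval data frames (`chrom`, `start`,
#'   `end`).
#' @param orthologs Optional ortholog pair table.
#' @param triplets Optional contact triplet table with possibly
#'   duplicated symmetric entries.
#' @return Data frame `input`, `level`, `message`; zero rows when all
#'   checks pass.
#' @export
validate_inputs <- function(genome, regions = list(), orthologs = NULL,
                            triplets = NULL) {
  findings <- list()
  add <- function(input, level, message)
    findings[[length(findings) + 1L]] <<-
      data.frame(input = input, level = level, message = message)
  for (nm in names(regions)) {
    df <- regions[[nm]]
    bad_chrom <- !df$chrom %in% names(genome)
    if (any(bad_chrom))
      add(nm, "fatal", paste0("unknown chromosome at line ",
                              which(bad_chrom)[1]))
    neg <- df$end <= df$start | df$start < 0
    if (any(neg))
      add(nm, "fatal", paste0("empty or negative interval at line ",
                              which(neg)[1]))
    over <- !bad_chrom & df$end > genome[df$chrom]
    if (any(over, na.rm = TRUE))
      add(nm, "fatal", paste0("interval beyond ", df$chrom[which(over)[1]],
                              " at line ", which(over)[1]))
    if (any(unlist(tapply(df$start, df$chrom, is.unsorted))))
      add(nm, "warning", "intervals not sorted; will be auto-sorted")
  }
  if (!is.null(orthologs)) {
    dup <- unique(c(orthologs$gene_a[duplicated(orthologs$gene_a)],
                    orthologs$gene_b[duplicated(orthologs$gene_b)]))
    if (length(dup))
      add("orthologs", "fatal",
          paste0("gene ids not one-to-one: ",
                 paste(utils::head(dup, 3), collapse = ", ")))
  }
  if (!is.null(triplets)) {
    i <- pmin(triplets$bin_i, triplets$bin_j)
    j <- pmax(triplets$bin_i, triplets$bin_j)
    key <- paste(i, j)
    bad <- tapply(triplets$value, key, function(v) length(unique(v)) > 1L)
    if (any(bad))
      add("triplets", "fatal",
          paste0("asymmetric entry for bin pair (",
                 sub(" ", ", ", names(bad)[bad][1]), ")"))
    if (any(triplets$value < 0))
      add("triplets", "fatal", "negative contact value")
  }
  if (!length(findings))
    return(data.frame(input = character(0), level = character(0),
                      message = character(0)))
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}
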