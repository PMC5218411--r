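#' Simulate the isochore structure of a genome (ground truth only)
#'
#' Draws, for each chromosome, a tiling of isochores: family succession
#' follows the configured Markov transition matrix (started from its
#' stationary distribution), lengths follow the family's lognormal law
#' truncated below at `min_isochore_length` and clipped to the
#' chromosome. The last drawn isochore is truncated (or the previous one
#' extended) so that the tiling covers `[0, chromosome_length)` exactly,
#' with no gaps or overlaps and adjacent families always distinct.
#'
#' This is the cheap, sequence-free part of [simulate_isochore_genome()];
#' downstream statistics that do not need nucleotides (domain and contact
#' simulation, synteny, CTCF) can start from it directly.
#'
#' @param config A [sim_config()].
#' @return A `ground_truth` list with element `isochores`: a data frame
#'   with columns `chrom`, `start`, `end` (0-based half-open bp),
#'   `family` and `gc` (the family's target GC%), plus the generating
#'   `config`.
#' @export
simulate_isochore_structure <- function(config) {
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, "isochores"), {
    out <- vector("list", config$n_chromosomes)
    for (ci in seq_len(config$n_chromosomes)) {
      chrom <- paste0("chr", ci)
      L <- config$chromosome_length
      starts <- ends <- numeric(0)
      fams <- integer(0)
      fam <- sample.int(5L, 1L, prob = transition_stationary(config$family_transition))
      pos <- 0
      repeat {
        len <- round(stats::rlnorm(1, config$family_length_params[fam, "meanlog"],
                                   config$family_length_params[fam, "sdlog"]))
        len <- max(len, config$min_isochore_length)
        if (pos + len > L) {
          rem <- L - pos
          if (rem >= config$min_isochore_length) {
            starts <- c(starts, pos); ends <- c(ends, L); fams <- c(fams, fam)
          } else if (length(ends)) {
            ends[length(ends)] <- L
          } else {
            starts <- 0; ends <- L; fams <- fam
          }
          break
        }
        starts <- c(starts, pos); ends <- c(ends, pos + len); fams <- c(fams, fam)
        pos <- pos + len
        fam <- sample.int(5L, 1L, prob = config$family_transition[fam, ])
        if (pos >= L) break
      }
      out[[ci]] <- data.frame(chrom = chrom, start = starts, end = ends,
                              family = .FAMILIES[fams],
                              gc = unname(config$family_gc_targets[fams]))
    }
    iso <- do.call(rbind, out)
    rownames(iso) <- NULL
    structure(list(isochores = iso,
                   genome = stats::setNames(rep(config$chromosome_length,
                                                config$n_chromosomes),
                                            paste0("chr", seq_len(config$n_chromosomes))),
                   config = config),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", length(x$genome), "chromosome(s),",
      nrow(x$isochores), "isochores\n")
  print(table(x$isochores$family)[.FAMILIES])
  invisible(x)
}

#' Simulate a mosaic isochore genome with sequence
#'
#' Generates nucleotide sequence on top of the isochore structure from
#' [simulate_isochore_structure()]. Within each isochore the sequence is
#' drawn i.i.d. per base, with the GC probability set per
#' `noise_window`-sized window to the family target plus Gaussian noise
#' (`window_noise_sd`, clipped to `[0, 100]`). Purines/pyrimidines are
#' symmetric (A/T and G/C equally likely within their class) and no
#' ambiguous bases are emitted. Identical configs (including the seed)
#' give byte-identical sequences and identical truth.
#'
#' @param config A [sim_config()].
#' @return A list with `sequences` (a [Biostrings::DNAStringSet], one
#'   record per chromosome) and `truth` (the `ground_truth`).
#' @examples
#' g <- simulate_isochore_genome(sim_config(seed = 7, n_chromosomes = 1,
#'                                          chromosome_length = 1e6))
#' names(g$sequences)
#' @export
simulate_isochore_genome <- function(config) {
  truth <- simulate_isochore_structure(config)
  seqs <- with_seed(stage_seed(config$seed, "sequence"), {
    lapply(names(truth$genome), function(chrom) {
      iso <- truth$isochores[truth$isochores$chrom == chrom, ]
      L <- truth$genome[[chrom]]
      # per-base GC probability, constant within noise windows
      gc_prob <- numeric(L)
      for (k in seq_len(nrow(iso))) {
        len <- iso$end[k] - iso$start[k]
        nw <- ceiling(len / config$noise_window)
        wgc <- clamp(iso$gc[k] + stats::rnorm(nw, 0, config$window_noise_sd),
                     0, 100) / 100
        widths <- rep(config$noise_window, nw)
        widths[nw] <- len - (nw - 1) * config$noise_window
        gc_prob[(iso$start[k] + 1):iso$end[k]] <- rep(wgc, times = widths)
      }
      is_gc <- stats::runif(L) < gc_prob
      other <- stats::runif(L) < 0.5
      # codes: A, T (AT class), C, G (GC class)
      bytes <- as.raw(c(65L, 84L, 67L, 71L))[1L + other + 2L * is_gc]
      rawToChar(bytes)
    })
  })
  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequences) <- names(truth$genome)
  list(sequences = sequences, truth = truth)
}

#' Simulate TADs and LADs from an isochore ground truth
#'
#' Concordant TADs are true isochores with endpoints perturbed by
#' Gaussian jitter (`tad_jitter_sd`), clipped to the chromosome;
#' endpoint pairs whose jitter would collapse or invert the interval are
#' re-drawn (with a warning). A `discordant_tad_fraction` of TADs is
#' instead placed uniformly at random, keeping lengths. LADs are the
#' true L1 and L2 isochores, each annotated with a nuclear-lamina
#' contact frequency drawn from the family's Beta law; under the default
#' parameters L1 contact frequencies stochastically dominate L2 ones,
#' reproducing the observation that high-CF lamina contacts belong
#' almost exclusively to the GC-poorest isochores.
#'
#' @param truth A `ground_truth` from [simulate_isochore_structure()].
#' @param config The generating [sim_config()].
#' @return List with data frames `tads` (`chrom`, `start`, `end`,
#'   `source` = source isochore row or `"discordant"`, `source_family`)
#'   and `lads` (`chrom`, `start`, `end`, `family`, `cf` in `[0, 1]`).
#' @export
simulate_domains <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  with_seed(stage_seed(config$seed, "domains"), {
    iso <- truth$isochores
    n <- nrow(iso)
    L <- truth$genome[iso$chrom]
    redraws <- 0L
    s <- e <- numeric(n)
    for (k in seq_len(n)) {
      repeat {
        sk <- clamp(round(iso$start[k] + stats::rnorm(1, 0, config$tad_jitter_sd)), 0, L[k])
        ek <- clamp(round(iso$end[k] + stats::rnorm(1, 0, config$tad_jitter_sd)), 0, L[k])
        if (ek - sk > 0) break
        redraws <- redraws + 1L
      }
      s[k] <- sk; e[k] <- ek
    }
    if (redraws > 0)
      warning(redraws, " jittered TAD interval(s) collapsed and were re-drawn")
    source <- as.character(seq_len(n))
    source_family <- iso$family
    n_disc <- round(config$discordant_tad_fraction * n)
    if (n_disc > 0) {
      pick <- sample.int(n, n_disc)
      len <- iso$end[pick] - iso$start[pick]
      s[pick] <- floor(stats::runif(n_disc) * (L[pick] - len))
      e[pick] <- s[pick] + len
      source[pick] <- "discordant"
      source_family[pick] <- NA_character_
    }
    tads <- data.frame(chrom = iso$chrom, start = s, end = e,
                       source = source, source_family = source_family)
    lad_iso <- iso[iso$family %in% names(config$lad_cf_params), ]
    cf <- vapply(seq_len(nrow(lad_iso)), function(k) {
      p <- config$lad_cf_params[[lad_iso$family[k]]]
      stats::rbeta(1, p[["alpha"]], p[["beta"]])
    }, numeric(1))
    lads <- data.frame(chrom = lad_iso$chrom, start = lad_iso$start,
                       end = lad_iso$end, family = lad_iso$family,
                       cf = if (nrow(lad_iso)) cf else numeric(0))
    rownames(lads) <- NULL
    list(tads = tads, lads = lads)
  })
}

#' Simulate CTCF binding-site positions
#'
#' Sites are placed by a homogeneous Poisson process within each true
#' isochore, at the per-Mb rate of the isochore's family. The default
#' rates form a strictly increasing gradient from L1 to H3, emulating
#' the observed decrease of CTCF site density towards GC-poor families.
#'
#' @param truth A `ground_truth`.
#' @param densities Named numeric, sites per Mb for each family.
#' @param seed Integer seed (defaults to a stage seed derived from the
#'   truth's config).
#' @return Data frame with columns `chrom`, `pos`, sorted by position.
#' @export
simulate_ctcf_sites <- function(truth,
                                densities = truth$config$ctcf_density,
                                seed = stage_seed(truth$config$seed, "ctcf")) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(densities < 0)) stop("densities must be >= 0")
  if (!all(.FAMILIES %in% names(densities)))
    stop("densities must be named for all five families")
  with_seed(seed, {
    iso <- truth$isochores
    counts <- stats::rpois(nrow(iso),
                           (iso$end - iso$start) / 1e6 * densities[iso$family])
    pos <- unlist(lapply(seq_len(nrow(iso)), function(k) {
      if (counts[k] == 0) return(numeric(0))
      floor(stats::runif(counts[k], iso$start[k], iso$end[k]))
    }))
    chrom <- rep(iso$chrom, counts)
    o <- order(chrom, pos)
    data.frame(chrom = chrom[o], pos = pos[o])
  })
}
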