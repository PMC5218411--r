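# Independent brute-force oracles and tiny fixture builders used across
# the test files. These deliberately avoid the package's own algorithms.

# O(n^2) / per-bp overlap oracle on a small integer genome.
brute_overlap <- function(a, b, mode) {
  if (mode == "count") {
    hit <- vapply(seq_len(nrow(a)), function(i) {
      any(vapply(seq_len(nrow(b)), function(j) {
        a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]
      }, logical(1)))
    }, logical(1))
    ids <- if (is.null(a$id)) seq_len(nrow(a)) else a$id
    length(unique(ids[hit]))
  } else {
    tot <- 0
    for (chrom in unique(c(a$chrom, b$chrom))) {
      cover <- function(df) {
        d <- df[df$chrom == chrom, , drop = FALSE]
        pos <- logical(0)
        for (k in seq_len(nrow(d))) {
          hi <- d$end[k]
          if (length(pos) < hi) pos[hi] <- FALSE
          pos[(d$start[k] + 1):d$end[k]] <- TRUE
        }
        pos
      }
      pa <- cover(a); pb <- cover(b)
      n <- min(length(pa), length(pb))
      if (n > 0)
        tot <- tot + sum(pa[seq_len(n)] & pb[seq_len(n)], na.rm = TRUE)
    }
    tot
  }
}

# Brute-force synteny chaining oracle: the validity of every candidate
# contiguous run [s, e] of the A-sorted table is checked wholesale (same
# chromosomes throughout, strictly monotone B positions); the emitted
# partition takes the longest valid run starting at each position and
# restarts at the first pair that cannot extend it.
brute_synteny <- function(pairs, min_genes = 3) {
  p <- pairs[order(pairs$chrom_a, pairs$start_a), ]
  n <- nrow(p)
  valid_run <- function(s, e) {
    if (length(unique(p$chrom_a[s:e])) > 1) return(FALSE)
    if (length(unique(p$chrom_b[s:e])) > 1) return(FALSE)
    b <- p$start_b[s:e]
    if (length(b) == 1) return(TRUE)
    all(diff(b) > 0) || all(diff(b) < 0)
  }
  out <- list()
  s <- 1
  while (s <= n) {
    e <- s
    while (e < n && valid_run(s, e + 1)) e <- e + 1
    if (e - s + 1 >= min_genes) {
      b <- p$start_b[s:e]
      out[[length(out) + 1]] <- list(
        genes = p$gene_a[s:e],
        orientation = if (b[length(b)] >= b[1]) "direct" else "inverted")
    }
    s <- e + 1
  }
  out
}

# Random ortholog table on small coordinates for fuzzing.
random_ortholog_table <- function(n, n_chrom_a = 2, n_chrom_b = 2) {
  sa <- sample.int(1000, n)
  sb <- sample.int(1000, n)
  data.frame(gene_a = sprintf("a%03d", seq_len(n)),
             chrom_a = sample(paste0("A", seq_len(n_chrom_a)), n, TRUE),
             start_a = sa, end_a = sa + 5,
             gene_b = sprintf("b%03d", seq_len(n)),
             chrom_b = sample(paste0("B", seq_len(n_chrom_b)), n, TRUE),
             start_b = sb, end_b = sb + 5,
             strand_b = sample(c("+", "-"), n, TRUE))
}

# Small helper: random disjoint-by-chance interval set on a toy genome.
random_regions <- function(n, genome, max_len = 50) {
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (genome[chrom] - len))
  data.frame(chrom = chrom, start = start, end = start + len)
}

# Shared small simulation config for fast tests.
quick_config <- function(seed, n_chromosomes = 1, chromosome_length = 5e6,
                         ...) {
  sim_config(seed = seed, n_chromosomes = n_chromosomes,
             chromosome_length = chromosome_length, ...)
}

# Complement of a set of intervals within a genome (used to build masks
# that confine random placement to a territory).
complement_regions <- function(df, genome) {
  out <- list()
  for (chrom in names(genome)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), ]
    edges_lo <- c(0, d$end)
    edges_hi <- c(d$start, genome[[chrom]])
    keep <- edges_hi > edges_lo
    if (any(keep))
      out[[length(out) + 1]] <- data.frame(chrom = chrom,
                                           start = edges_lo[keep],
                                           end = edges_hi[keep])
  }
  do.call(rbind, out)
}
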