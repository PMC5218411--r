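#' Simulate an ortholog table with planted synteny blocks
#'
#' Species A genes are laid out at regular spacing along each chromosome
#' of the truth genome and grouped into consecutive blocks of
#' `genes_per_block` genes. Each block is transported to species B as a
#' rigid (optionally mirrored) copy: consecutive A blocks alternate
#' between species-B chromosomes, the blocks assigned to one B
#' chromosome are laid out in a random order, and each block is
#' independently inverted with probability 0.5. Because two A-adjacent
#' blocks never share a B chromosome, the planted partition is exactly
#' recoverable by order-conserved chaining. Species B GC equals the
#' source isochore GC plus Gaussian noise (`ortholog_gc_noise_sd`),
#' drawn once per (isochore x block) piece.
#'
#' With `shuffle = FALSE` the table is fully collinear on a single B
#' chromosome with no inversions (a degenerate layout useful for
#' testing).
#'
#' @param truth A `ground_truth` for species A.
#' @param config The generating [sim_config()]; `genes_per_block` must
#'   be at least 3 or the planted blocks would be undetectable under
#'   the three-ortholog rule.
#' @param shuffle Permute and invert blocks (default `TRUE`).
#' @param n_chrom_b Number of species-B chromosomes used when shuffling.
#' @return A list with:
#' \describe{
#'   \item{pairs}{ortholog table: `gene_a`, `chrom_a`, `start_a`,
#'     `end_a`, `gene_b`, `chrom_b`, `start_b`, `end_b`, `strand_b`.}
#'   \item{blocks}{planted truth: one row per block with both spans and
#'     `orientation` (`direct`/`inverted`), plus a `genes` list column.}
#'   \item{b_regions}{species-B GC regions: `chrom`, `start`, `end`,
#'     `gc` (projected isochore pieces with noise).}
#'   \item{b_genome}{named vector of species-B chromosome lengths.}
#' }
#' @export
simulate_orthologs <- function(truth, config = truth$config,
                               shuffle = TRUE, n_chrom_b = 2L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (config$genes_per_block < 3L)
    stop("genes_per_block must be >= 3 (blocks of fewer orthologs are ",
         "undetectable under the >= 3 ortholog rule)")
  if (!shuffle) n_chrom_b <- 1L
  if (shuffle && n_chrom_b < 2L)
    stop("shuffled layouts need n_chrom_b >= 2 so that consecutive blocks ",
         "never share a species-B chromosome")
  gene_w <- 2e3
  with_seed(stage_seed(config$seed, "orthologs"), {
    blocks <- list(); genes <- list(); bid <- 0L
    for (chrom in names(truth$genome)) {
      L <- truth$genome[[chrom]]
      n_genes <- floor(L / config$gene_spacing)
      n_blocks <- n_genes %/% config$genes_per_block
      if (n_blocks == 0L) next
      n_genes <- n_blocks * config$genes_per_block
      gs <- round(config$gene_spacing * (seq_len(n_genes) - 0.5))
      for (b in seq_len(n_blocks)) {
        bid <- bid + 1L
        idx <- ((b - 1L) * config$genes_per_block + 1L):(b * config$genes_per_block)
        genes[[bid]] <- data.frame(
          block = bid,
          gene_a = sprintf("gA%05d", (bid - 1L) * config$genes_per_block +
                             seq_along(idx)),
          chrom_a = chrom, start_a = gs[idx], end_a = gs[idx] + gene_w)
        blocks[[bid]] <- data.frame(
          block_id = bid, chrom_a = chrom,
          start_a = gs[idx[1]], end_a = gs[idx[length(idx)]] + gene_w,
          # consecutive A blocks alternate B chromosomes
          chrom_b = paste0("chrB", ((b - 1L) %% n_chrom_b) + 1L),
          orientation = if (shuffle && stats::runif(1) < 0.5) "inverted" else "direct")
      }
    }
    blocks <- do.call(rbind, blocks)
    blocks$start_b <- NA_real_; blocks$end_b <- NA_real_
    b_genome <- numeric(0)
    if (!shuffle) {
      # identity layout: species B is a verbatim coordinate copy, one B
      # chromosome mirroring each A chromosome
      blocks$chrom_b <- paste0("B_", blocks$chrom_a)
      blocks$start_b <- blocks$start_a
      blocks$end_b <- blocks$end_a
      for (cb in unique(blocks$chrom_b))
        b_genome[cb] <- truth$genome[[sub("^B_", "", cb)]]
    } else {
      # blocks of each B chromosome laid head-to-tail in permuted order
      gap_b <- 1e5
      for (cb in unique(blocks$chrom_b)) {
        rows <- which(blocks$chrom_b == cb)
        ord <- sample(rows)
        pos <- gap_b
        for (r in ord) {
          len <- blocks$end_a[r] - blocks$start_a[r]
          blocks$start_b[r] <- pos
          blocks$end_b[r] <- pos + len
          pos <- pos + len + gap_b
        }
        b_genome[cb] <- pos
      }
    }
    # gene coordinates in B: rigid copy, mirrored for inverted blocks
    pairs <- do.call(rbind, genes)
    pb <- blocks[pairs$block, ]
    inv <- pb$orientation == "inverted"
    pairs$gene_b <- sub("^gA", "gB", pairs$gene_a)
    pairs$chrom_b <- pb$chrom_b
    pairs$start_b <- ifelse(inv,
                            pb$start_b + (pb$end_a - pairs$end_a),
                            pb$start_b + (pairs$start_a - pb$start_a))
    pairs$end_b <- pairs$start_b + gene_w
    pairs$strand_b <- ifelse(inv, "-", "+")
    # species-B GC regions: isochore pieces projected through each block
    breg <- list()
    iso <- truth$isochores
    for (r in seq_len(nrow(blocks))) {
      ii <- iso$chrom == blocks$chrom_a[r] &
        iso$end > blocks$start_a[r] & iso$start < blocks$end_a[r]
      piece <- iso[ii, , drop = FALSE]
      if (!nrow(piece)) next
      ps <- pmax(piece$start, blocks$start_a[r])
      pe <- pmin(piece$end, blocks$end_a[r])
      if (blocks$orientation[r] == "direct") {
        bs <- blocks$start_b[r] + (ps - blocks$start_a[r])
        be <- blocks$start_b[r] + (pe - blocks$start_a[r])
      } else {
        bs <- blocks$start_b[r] + (blocks$end_a[r] - pe)
        be <- blocks$start_b[r] + (blocks$end_a[r] - ps)
      }
      breg[[length(breg) + 1L]] <- data.frame(
        chrom = blocks$chrom_b[r], start = bs, end = be,
        gc = clamp(piece$gc + stats::rnorm(nrow(piece), 0,
                                           config$ortholog_gc_noise_sd),
                   0, 100))
    }
    b_regions <- do.call(rbind, breg)
    b_regions <- b_regions[order(b_regions$chrom, b_regions$start), ]
    rownames(b_regions) <- NULL
    members <- split(pairs$gene_a, pairs$block)
    blocks$genes <- I(unname(members[as.character(blocks$block_id)]))
    pairs$block <- NULL
    rownames(pairs) <- NULL
    list(pairs = pairs, blocks = blocks, b_regions = b_regions,
         b_genome = b_genome)
  })
}

#' Write / read an ortholog pair table
#'
#' Plain TSV with the columns `gene_a`, `chrom_a`, `start_a`, `end_a`,
#' `gene_b`, `chrom_b`, `start_b`, `end_b`, `strand_b` (0-based
#' half-open coordinates).
#'
#' @param pairs Ortholog data frame.
#' @param path File path.
#' @return `read_orthologs` returns the data frame; `write_orthologs`
#'   returns `path` invisibly.
#' @export
write_orthologs <- function(pairs, path) {
  cols <- c("gene_a", "chrom_a", "start_a", "end_a",
            "gene_b", "chrom_b", "start_b", "end_b", "strand_b")
  utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_orthologs
#' @export
read_orthologs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
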