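# Synteny blocks from ortholog pair tables, orthologous isochores and
# cross-species GC correlation.

#' Build synteny blocks from an ortholog pair table
#'
#' Pairs are sorted by `(chrom_a, start_a)` and chained greedily: a
#' chain grows while the next pair stays on the same species-A and
#' species-B chromosome (and the same B chromosome arm when a
#' centromere table is supplied) and keeps the B positions strictly
#' monotonic in the chain's orientation. The orientation (direct =
#' ascending, inverted = descending B positions) is fixed by the chain's
#' first two members. Any violation closes the chain and opens a new one
#' at the violating pair. Chains with at least `min_genes` members are
#' emitted as blocks.
#'
#' Descending B order counts as conserved (inverted) order by default;
#' `direct_only = TRUE` restricts blocks to ascending order. An optional
#' `max_gap` closes chains across large inter-gene gaps in either
#' species.
#'
#' @param pairs Ortholog data frame with columns `gene_a`, `chrom_a`,
#'   `start_a`, `end_a`, `gene_b`, `chrom_b`, `start_b`, `end_b`
#'   (and optionally `strand_b`); each gene id must appear exactly once.
#' @param min_genes Minimum chain length to emit a block (the canonical
#'   rule is at least 3 orthologs).
#' @param arms_b Optional data frame `chrom`, `centromere_pos` used to
#'   annotate species-B arms (`p` below the centromere, `q` above).
#' @param direct_only Reject inverted chains.
#' @param max_gap Optional maximum inter-gene gap in bp.
#' @return Data frame with one row per block: `block_id`, `chrom_a`,
#'   `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b`, `arm_b`,
#'   `orientation`, `n_genes`, and a `genes` list column of member
#'   `gene_a` ids (in A order).
#' @export
build_synteny_blocks <- function(pairs, min_genes = 3L, arms_b = NULL,
                                 direct_only = FALSE, max_gap = NULL) {
  stopifnot(min_genes >= 2L)
  dup <- c(pairs$gene_a[duplicated(pairs$gene_a)],
           pairs$gene_b[duplicated(pairs$gene_b)])
  if (length(dup))
    stop("ortholog table is not one-to-one; duplicated ids: ",
         paste(unique(dup), collapse = ", "))
  p <- pairs[order(pairs$chrom_a, pairs$start_a), ]
  arm <- rep("unknown", nrow(p))
  if (!is.null(arms_b)) {
    cen <- stats::setNames(arms_b$centromere_pos, arms_b$chrom)
    known <- p$chrom_b %in% names(cen)
    arm[known] <- ifelse(p$start_b[known] < cen[p$chrom_b[known]], "p", "q")
  }
  chains <- list()
  cur <- 1L  # chain start index
  orient <- 0L  # 0 unfixed, +1 direct, -1 inverted
  close_chain <- function(from, to) {
    if (to - from + 1L >= min_genes)
      chains[[length(chains) + 1L]] <<- c(from, to)
  }
  n <- nrow(p)
  if (n == 0L)
    return(.empty_blocks())
  for (k in seq_len(n)[-1]) {
    prev <- k - 1L
    violation <- p$chrom_a[k] != p$chrom_a[prev] ||
      p$chrom_b[k] != p$chrom_b[prev] ||
      arm[k] != arm[prev]
    if (!violation && !is.null(max_gap))
      violation <- (p$start_a[k] - p$end_a[prev] > max_gap) ||
        (abs(p$start_b[k] - p$start_b[prev]) > max_gap)
    if (!violation) {
      step <- sign(p$start_b[k] - p$start_b[prev])
      if (step == 0) violation <- TRUE  # tied B positions break the chain
      else if (orient == 0L) {
        if (direct_only && step < 0) violation <- TRUE else orient <- step
      } else if (step != orient) violation <- TRUE
    }
    if (violation) {
      close_chain(cur, prev)
      cur <- k
      orient <- 0L
    }
  }
  close_chain(cur, n)
  if (!length(chains)) return(.empty_blocks())
  rows <- lapply(seq_along(chains), function(i) {
    span <- chains[[i]]
    m <- p[span[1]:span[2], ]
    data.frame(block_id = i,
               chrom_a = m$chrom_a[1],
               start_a = min(m$start_a), end_a = max(m$end_a),
               chrom_b = m$chrom_b[1],
               start_b = min(m$start_b), end_b = max(m$end_b),
               arm_b = arm[chains[[i]][1]],
               orientation = if (m$start_b[nrow(m)] >= m$start_b[1])
                 "direct" else "inverted",
               n_genes = nrow(m))
  })
  out <- do.call(rbind, rows)
  out$genes <- I(lapply(chains, function(span) p$gene_a[span[1]:span[2]]))
  rownames(out) <- NULL
  out
}

.empty_blocks <- function() {
  out <- data.frame(block_id = integer(0), chrom_a = character(0),
                    start_a = numeric(0), end_a = numeric(0),
                    chrom_b = character(0), start_b = numeric(0),
                    end_b = numeric(0), arm_b = character(0),
                    orientation = character(0), n_genes = integer(0))
  out$genes <- I(list())
  out
}

#' Summary statistics of synteny block spans
#'
#' @param blocks Output of [build_synteny_blocks()].
#' @return List `count`, `mean_span`, `min_span`, `max_span` (species-A
#'   span lengths in bp; NA when there are no blocks).
#' @export
block_stats <- function(blocks) {
  if (!nrow(blocks))
    return(list(count = 0L, mean_span = NA_real_, min_span = NA_real_,
                max_span = NA_real_))
  span <- blocks$end_a - blocks$start_a
  list(count = nrow(blocks), mean_span = mean(span),
       min_span = min(span), max_span = max(span))
}

#' Orthologous isochores through synteny blocks
#'
#' Intersects species-A isochores with the species-A spans of synteny
#' blocks; an isochore covered over at least `min_overlap_frac` of its
#' length by one block is projected into species B by linear
#' proportional mapping of the intersected interval onto the block's B
#' span (mirrored for inverted blocks), and its species-B GC is read as
#' the overlap-weighted mean of the supplied B GC regions.
#'
#' @param blocks Output of [build_synteny_blocks()].
#' @param isochores_a Species-A isochores (`chrom`, `start`, `end`,
#'   `family`, and `gc` or `mean_gc`).
#' @param gc_b Species-B GC table (`chrom`, `start`, `end`, `gc`).
#' @param min_overlap_frac Minimum fraction of the isochore covered by a
#'   block (default 0.5; avoids sliver intersections). When several
#'   blocks qualify the largest overlap wins.
#' @return Data frame of pairs: isochore coordinates, `family`, `gc_a`,
#'   projected `chrom_b`, `start_b`, `end_b`, `gc_b`, `block_id`;
#'   attribute `n_excluded` counts isochores matching no block.
#' @export
orthologous_isochores <- function(blocks, isochores_a, gc_b,
                                  min_overlap_frac = 0.5) {
  iso <- isochores_a
  gc_col <- if ("gc" %in% names(iso)) "gc" else "mean_gc"
  out <- list(); excluded <- 0L
  for (k in seq_len(nrow(iso))) {
    cand <- blocks[blocks$chrom_a == iso$chrom[k] &
                     blocks$end_a > iso$start[k] &
                     blocks$start_a < iso$end[k], , drop = FALSE]
    if (!nrow(cand)) { excluded <- excluded + 1L; next }
    ov <- pmin(cand$end_a, iso$end[k]) - pmax(cand$start_a, iso$start[k])
    best <- which.max(ov)
    if (ov[best] < min_overlap_frac * (iso$end[k] - iso$start[k])) {
      excluded <- excluded + 1L; next
    }
    b <- cand[best, ]
    s <- pmax(b$start_a, iso$start[k]); e <- pmin(b$end_a, iso$end[k])
    scale <- (b$end_b - b$start_b) / (b$end_a - b$start_a)
    if (b$orientation == "direct") {
      bs <- b$start_b + (s - b$start_a) * scale
      be <- b$start_b + (e - b$start_a) * scale
    } else {
      bs <- b$start_b + (b$end_a - e) * scale
      be <- b$start_b + (b$end_a - s) * scale
    }
    gcb <- .weighted_gc(gc_b, b$chrom_b, bs, be)
    out[[length(out) + 1L]] <- data.frame(
      chrom_a = iso$chrom[k], start_a = iso$start[k], end_a = iso$end[k],
      family = iso$family[k], gc_a = iso[[gc_col]][k],
      chrom_b = b$chrom_b, start_b = round(bs), end_b = round(be),
      gc_b = gcb, block_id = b$block_id)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom_a = character(0), start_a = numeric(0),
               end_a = numeric(0), family = character(0),
               gc_a = numeric(0), chrom_b = character(0),
               start_b = numeric(0), end_b = numeric(0),
               gc_b = numeric(0), block_id = integer(0))
  rownames(res) <- NULL
  attr(res, "n_excluded") <- excluded
  res
}

.weighted_gc <- function(gc_b, chrom, s, e) {
  g <- gc_b[gc_b$chrom == chrom & gc_b$end > s & gc_b$start < e, ,
            drop = FALSE]
  if (!nrow(g)) return(NA_real_)
  w <- pmin(g$end, e) - pmax(g$start, s)
  sum(g$gc * w) / sum(w)
}

#' Cross-species GC correlation of orthologous regions
#'
#' Pearson and Spearman correlations between species-A and species-B GC
#' of orthologous isochores, with a Fisher-z 95% confidence interval
#' for the Pearson coefficient.
#'
#' @param pairs Output of [orthologous_isochores()], or any data frame
#'   with columns `gc_a` and `gc_b` (NA pairs dropped).
#' @return List `pearson_r`, `spearman_rho`, `n`, `conf_low`,
#'   `conf_high`.
#' @export
gc_correlation <- function(pairs) {
  ok <- stats::complete.cases(pairs$gc_a, pairs$gc_b)
  a <- pairs$gc_a[ok]; b <- pairs$gc_b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in one GC vector; correlation undefined")
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_, n = n,
                conf_low = NA_real_, conf_high = NA_real_))
  }
  r <- stats::cor(a, b)
  rho <- stats::cor(a, b, method = "spearman")
  se <- 1 / sqrt(n - 3)
  ci <- tanh(atanh(r) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(pearson_r = r, spearman_rho = rho, n = n,
       conf_low = ci[1], conf_high = ci[2])
}
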