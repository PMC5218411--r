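# Region sets: named interval collections on a genome with known
# chromosome lengths. The plain-data-frame representation keeps the
# permutation loops fast; BED input/output goes through rtracklayer.

#' Create a region set
#'
#' @param regions Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open bp); an optional `id` column identifies parent
#'   intervals (rows sharing an id are fragments of one interval, as
#'   produced by circular wrapping).
#' @param genome Named numeric vector of chromosome lengths.
#' @param name Optional set name.
#' @param mask Optional data frame of excluded intervals (same columns).
#' @return Object of class `region_set`.
#' @examples
#' rs <- region_set(data.frame(chrom = "chr1", start = 0, end = 100),
#'                  genome = c(chr1 = 1000))
#' @export
region_set <- function(regions, genome, name = "", mask = NULL) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)),
            !is.null(names(genome)))
  regions <- as.data.frame(regions)
  if (nrow(regions)) {
    if (!all(regions$chrom %in% names(genome)))
      stop("regions on chromosomes absent from the genome: ",
           paste(setdiff(unique(regions$chrom), names(genome)), collapse = ", "))
    bad <- regions$start < 0 | regions$end <= regions$start |
      regions$end > genome[regions$chrom]
    if (any(bad))
      stop("invalid interval(s) at row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (is.null(regions$id)) regions$id <- seq_len(nrow(regions))
  if (!is.null(mask)) mask <- as.data.frame(mask)
  structure(list(name = name, regions = regions[c("chrom", "start", "end", "id")],
                 genome = genome, mask = mask),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", if (nzchar(x$name)) x$name else "(unnamed)", "|",
      length(unique(x$regions$id)), "interval(s) on",
      length(x$genome), "chromosome(s)\n")
  invisible(x)
}

#' @export
as.data.frame.region_set <- function(x, ...) x$regions

# ---- internal flat-coordinate machinery -------------------------------
# Chromosomes are concatenated on one axis (offset by cumulated lengths)
# so that sorted-disjoint interval algebra needs no per-chromosome split.

.chrom_offsets <- function(genome) {
  off <- cumsum(c(0, as.numeric(genome)))[seq_along(genome)]
  names(off) <- names(genome)
  off
}

.flatten <- function(df, offsets) {
  if (!nrow(df)) return(data.frame(s = numeric(0), e = numeric(0),
                                   id = integer(0)))
  o <- offsets[df$chrom]
  data.frame(s = o + df$start, e = o + df$end,
             id = if (is.null(df$id)) seq_len(nrow(df)) else df$id)
}

# Merge to sorted disjoint intervals (drops ids).
.reduce_flat <- function(s, e) {
  if (!length(s)) return(list(s = numeric(0), e = numeric(0)))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  cm <- cummax(e)
  new_grp <- c(TRUE, s[-1] > cm[-length(cm)])
  grp <- cumsum(new_grp)
  list(s = s[new_grp], e = as.numeric(tapply(e, grp, max)))
}

# Total intersection bp between interval set (as, ae) and a *sorted
# disjoint* set (bs, be).
.isect_bp_flat <- function(as, ae, bs, be) {
  if (!length(as) || !length(bs)) return(0)
  j1 <- findInterval(as, be) + 1L        # first b with be > as
  j2 <- findInterval(ae - 1, bs)         # last b with bs < ae
  nh <- pmax(0L, j2 - j1 + 1L)
  if (!any(nh > 0)) return(0)
  ai <- rep.int(seq_along(as), nh)
  k <- sequence(nh) + rep.int(j1 - 1L, nh)
  sum(pmin(ae[ai], be[k]) - pmax(as[ai], bs[k]))
}

# Which rows of (as, ae) overlap the sorted disjoint set (bs, be)?
.overlaps_flat <- function(as, ae, bs, be) {
  if (!length(as) || !length(bs)) return(logical(length(as)))
  j1 <- findInterval(as, be) + 1L
  j2 <- findInterval(ae - 1, bs)
  j2 >= j1
}

.check_same_genome <- function(A, B) {
  if (!identical(names(A$genome), names(B$genome)) ||
      !isTRUE(all.equal(unname(as.numeric(A$genome)),
                        unname(as.numeric(B$genome)))))
    stop("region sets are defined on different genomes")
}

#' Overlap statistic between two region sets
#'
#' The evaluation function of the permutation test. `count` mode counts
#' the A intervals overlapping at least 1 bp of the union of B (a
#' wrapped interval counts once); `basepair` mode is the total bp of
#' intersection between the two unions. Count mode saturates when B
#' tiles the genome, which is why isochore-versus-domain tests default
#' to basepair mode.
#'
#' @param A,B `region_set`s on the same genome.
#' @param mode `"count"` or `"basepair"`.
#' @return A single number.
#' @examples
#' g <- c(chr1 = 1000)
#' A <- region_set(data.frame(chrom = "chr1", start = 0, end = 100), g)
#' B <- region_set(data.frame(chrom = "chr1", start = 50, end = 150), g)
#' overlap_statistic(A, B, "count")
#' overlap_statistic(A, B, "basepair")
#' @export
overlap_statistic <- function(A, B, mode = c("count", "basepair")) {
  mode <- match.arg(mode)
  .check_same_genome(A, B)
  off <- .chrom_offsets(A$genome)
  fa <- .flatten(A$regions, off)
  rb <- .reduce_flat(.flatten(B$regions, off)$s, .flatten(B$regions, off)$e)
  .overlap_stat_flat(fa, rb, mode)
}

.overlap_stat_flat <- function(fa, rb, mode) {
  if (mode == "count") {
    hit <- .overlaps_flat(fa$s, fa$e, rb$s, rb$e)
    length(unique(fa$id[hit]))
  } else {
    ra <- .reduce_flat(fa$s, fa$e)
    .isect_bp_flat(ra$s, ra$e, rb$s, rb$e)
  }
}

#' Randomize a region set
#'
#' `uniform` re-places every interval uniformly on its own chromosome,
#' preserving its length, avoiding the mask and previously placed
#' intervals: placement samples directly from the remaining feasible
#' start space (longest intervals first), so it is exact and never
#' loops; an empty feasible space is an error naming the chromosome.
#' `circular` shifts all intervals of a chromosome by one uniform
#' offset, wrapping at the chromosome end; a wrapping interval is stored
#' as two fragments sharing the parent `id`, so the interval count and
#' length multiset (per id) are preserved exactly.
#'
#' @param RS A `region_set`.
#' @param scheme `"uniform"` or `"circular"`.
#' @param seed Optional integer seed.
#' @param offset Optional named (or scalar) circular offset per
#'   chromosome, overriding the random draw (used for degenerate tests).
#' @return A new `region_set`.
#' @export
randomize_regions <- function(RS, scheme = c("uniform", "circular"),
                              seed = NULL, offset = NULL) {
  scheme <- match.arg(scheme)
  with_seed(seed, {
    out <- switch(scheme,
                  uniform = .randomize_uniform(RS$regions, RS$genome, RS$mask),
                  circular = .shift_circular(RS$regions, RS$genome, offset))
    region_set(out, RS$genome, name = RS$name, mask = RS$mask)
  })
}

.randomize_uniform <- function(regions, genome, mask = NULL) {
  res <- regions
  for (chrom in unique(regions$chrom)) {
    rows <- which(regions$chrom == chrom)
    L <- genome[[chrom]]
    # free gaps: chromosome minus the mask
    gs <- 0; ge <- L
    if (!is.null(mask) && any(mask$chrom == chrom)) {
      m <- .reduce_flat(mask$start[mask$chrom == chrom],
                        mask$end[mask$chrom == chrom])
      gs <- c(0, m$e); ge <- c(m$s, L)
      keep <- ge > gs
      gs <- gs[keep]; ge <- ge[keep]
    }
    lens <- regions$end[rows] - regions$start[rows]
    for (r in rows[order(-lens)]) {
      len <- regions$end[r] - regions$start[r]
      navail <- pmax(0, ge - gs - len + 1)
      tot <- sum(navail)
      if (tot <= 0)
        stop("no feasible placement for a ", len, " bp interval on ", chrom)
      u <- min(floor(stats::runif(1) * tot), tot - 1)
      g <- which(cumsum(navail) > u)[1]
      before <- if (g > 1) sum(navail[seq_len(g - 1)]) else 0
      start <- gs[g] + (u - before)
      res$start[r] <- start; res$end[r] <- start + len
      # split the gap around the placed interval
      gs <- c(gs[-g], gs[g], start + len)
      ge <- c(ge[-g], start, ge[g])
      keep <- ge > gs
      gs <- gs[keep]; ge <- ge[keep]
    }
  }
  res
}

.shift_circular <- function(regions, genome, offset = NULL) {
  pieces <- list()
  for (chrom in unique(regions$chrom)) {
    rows <- which(regions$chrom == chrom)
    L <- genome[[chrom]]
    d <- if (is.null(offset)) floor(stats::runif(1) * L)
         else if (!is.null(names(offset))) offset[[chrom]] else offset
    d <- ((d %% L) + L) %% L
    s <- (regions$start[rows] + d) %% L
    e <- s + (regions$end[rows] - regions$start[rows])
    id <- regions$id[rows]
    wrap <- e > L
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = chrom,
      start = c(s[!wrap], s[wrap], rep(0, sum(wrap))),
      end = c(e[!wrap], rep(L, sum(wrap)), e[wrap] - L),
      id = c(id[!wrap], id[wrap], id[wrap]))
  }
  out <- do.call(rbind, pieces)
  out[out$end > out$start, , drop = FALSE]
}
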