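# Sliding-window GC profiles and isochore segmentation.

#' Isochore family GC boundaries
#'
#' The four GC% cutpoints separating the five families, under the
#' classical "fixed" family ranges (L1 < 37, L2 37--41, H1 41--46,
#' H2 46--53, H3 > 53) or the "extended" ranges (each cutpoint relaxed
#' by one GC%), which tolerate minimal trespassing of the 46% H1 upper
#' threshold. Assignment intervals are half-open `[low, high)`, so a GC
#' of exactly 46 falls in H2 under fixed boundaries.
#'
#' @param mode `"fixed"` or `"extended"`.
#' @param cutpoints Optional numeric(4), strictly increasing GC%
#'   cutpoints overriding the mode's defaults.
#' @return An object of class `family_boundaries`.
#' @examples
#' assign_family(c(30, 46, 60), family_boundaries("fixed"))
#' @export
family_boundaries <- function(mode = c("fixed", "extended"), cutpoints = NULL) {
  mode <- match.arg(mode)
  if (is.null(cutpoints))
    cutpoints <- switch(mode,
                        fixed = c(37, 41, 46, 53),
                        extended = c(36, 40, 47, 54))
  stopifnot(length(cutpoints) == 4L, all(diff(cutpoints) > 0),
            all(cutpoints > 0 & cutpoints < 100))
  structure(list(mode = mode, cutpoints = cutpoints),
            class = "family_boundaries")
}

#' @export
print.family_boundaries <- function(x, ...) {
  cat("<family_boundaries>", x$mode, "| cutpoints:",
      paste(x$cutpoints, collapse = " / "), "GC%\n")
  invisible(x)
}

#' Assign isochore family labels from GC content
#'
#' A total, monotone step function of GC: family `f` is assigned when GC
#' lies in the half-open interval `[low_f, high_f)`; L1 starts at 0 and
#' H3 includes 100.
#'
#' @param gc Numeric GC% values in `[0, 100]` (NA allowed, returns NA).
#' @param boundaries A [family_boundaries()].
#' @return Ordered factor with levels `L1 < L2 < H1 < H2 < H3`.
#' @export
assign_family <- function(gc, boundaries = family_boundaries()) {
  stopifnot(inherits(boundaries, "family_boundaries"))
  if (any(gc < 0 | gc > 100, na.rm = TRUE))
    stop("gc values must lie in [0, 100]")
  idx <- findInterval(gc, boundaries$cutpoints) + 1L
  factor(.FAMILIES[idx], levels = .FAMILIES, ordered = TRUE)
}

#' Compute a sliding-window GC profile
#'
#' GC% per window is `100 * (G + C) / (A + C + G + T)`, i.e. computed
#' over unambiguous bases only. Windows whose non-ACGT fraction exceeds
#' `n_policy` are masked (GC = NA). A trailing partial window is
#' included, flagged `partial`, when it covers at least half a window.
#'
#' @param sequence A nucleotide string, [Biostrings::DNAString] or a
#'   length-1 [Biostrings::DNAStringSet].
#' @param window Window size in bp.
#' @param step Step between window starts in bp; defaults to `window`
#'   (non-overlapping tiling, the form used for segmentation).
#' @param n_policy Maximum tolerated non-ACGT fraction before masking.
#' @param chrom Optional chromosome name attached to the profile.
#' @param strict Error (instead of one partial window) when `window`
#'   exceeds the sequence length.
#' @return A `gc_profile`: data frame with columns `start`, `end`, `gc`
#'   (NA when masked), `bases` (ACGT count), `masked`, `partial`, and
#'   attributes `chrom`, `window`, `step`.
#' @examples
#' compute_gc_profile("ACGTACGTGGCC", window = 4)$gc
#' @export
compute_gc_profile <- function(sequence, window, step = window,
                               n_policy = 0.5, chrom = NA_character_,
                               strict = FALSE) {
  stopifnot(window >= 1, step >= 1)
  if (inherits(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    if (is.na(chrom) && !is.null(names(sequence))) chrom <- names(sequence)[1]
    sequence <- sequence[[1]]
  }
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  L <- length(sequence)
  if (L == 0) stop("sequence is empty")
  if (window > L) {
    if (strict) stop("window (", window, ") exceeds sequence length (", L, ")")
    starts <- 0
  } else {
    starts <- seq(0, L - window, by = step)
    nxt <- starts[length(starts)] + step
    if (nxt < L && (L - nxt) >= window / 2) starts <- c(starts, nxt)
  }
  ends <- pmin(starts + window, L)
  v <- Biostrings::Views(sequence, start = starts + 1, end = ends)
  freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"),
                                      OR = 0)
  bases <- rowSums(freq)
  width <- ends - starts
  masked <- (width - bases) / width > n_policy
  gc <- ifelse(bases > 0 & !masked,
               100 * (freq[, "C"] + freq[, "G"]) / bases, NA_real_)
  masked <- masked | bases == 0
  out <- data.frame(start = starts, end = ends, gc = gc, bases = bases,
                    masked = masked, partial = width < window)
  structure(out, chrom = chrom, window = window, step = step,
            n_policy = n_policy, class = c("gc_profile", "data.frame"))
}

#' Segment a GC profile into isochores
#'
#' Consecutive windows with the same assigned family are merged;
#' segments shorter than `min_size` are then absorbed, smallest first,
#' into the flanking neighbour whose mean GC is nearer (left neighbour
#' on an exact tie), the merged segment's GC and family being recomputed
#' from the pooled windows, until every segment reaches `min_size` or
#' has no neighbour to merge with. Masked windows break segments and are
#' never covered by output isochores; a run consisting of one
#' sub-minimal segment is kept and flagged `"short"`.
#'
#' Using non-overlapping windows (the default step of
#' [compute_gc_profile()]) is recommended for segmentation since
#' overlapping windows would double-count sequence.
#'
#' @param profile A `gc_profile`.
#' @param boundaries A [family_boundaries()].
#' @param min_size Minimum isochore size in bp (default 200 kb, the
#'   lower edge of the chromatin-domain size range).
#' @return Data frame with columns `chrom`, `start`, `end`, `mean_gc`,
#'   `family`, `n_windows`, `flag`; adjacent rows always differ in
#'   family within an unmasked run.
#' @export
segment_isochores <- function(profile, boundaries = family_boundaries(),
                              min_size = 2e5) {
  stopifnot(inherits(profile, "gc_profile"))
  ok <- !profile$masked
  if (!any(ok)) {
    warning("profile is fully masked; no isochores")
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_gc = numeric(0),
                      family = character(0), n_windows = integer(0),
                      flag = character(0)))
  }
  chrom <- attr(profile, "chrom")
  run_id <- cumsum(c(TRUE, diff(ok) != 0))
  out <- list()
  for (rid in unique(run_id[ok])) {
    w <- profile[run_id == rid & ok, , drop = FALSE]
    segs <- .segment_run(w, boundaries, min_size)
    segs$chrom <- chrom
    out[[length(out) + 1L]] <- segs
  }
  res <- do.call(rbind, out)
  res <- res[, c("chrom", "start", "end", "mean_gc", "family",
                 "n_windows", "flag")]
  rownames(res) <- NULL
  res
}

# Segment one contiguous unmasked run of windows.
.segment_run <- function(w, boundaries, min_size) {
  fam <- as.integer(assign_family(w$gc, boundaries))
  # initial segments: runs of equal family
  r <- rle(fam)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  seg <- data.frame(lo = lo, hi = hi)
  seg_stats <- function(s) {
    idx <- s$lo:s$hi
    wt <- w$bases[idx]
    list(gc = sum(w$gc[idx] * wt) / sum(wt),
         start = w$start[s$lo], end = w$end[s$hi])
  }
  recompute <- function(seg) {
    st <- lapply(seq_len(nrow(seg)), function(k) seg_stats(seg[k, ]))
    seg$start <- vapply(st, `[[`, numeric(1), "start")
    seg$end <- vapply(st, `[[`, numeric(1), "end")
    seg$gc <- vapply(st, `[[`, numeric(1), "gc")
    seg$fam <- as.integer(assign_family(seg$gc, boundaries))
    seg
  }
  seg <- recompute(seg)
  repeat {
    # merge adjacent equal families
    if (nrow(seg) > 1) {
      grp <- cumsum(c(TRUE, diff(seg$fam) != 0))
      if (max(grp) < nrow(seg)) {
        seg <- data.frame(lo = tapply(seg$lo, grp, min),
                          hi = tapply(seg$hi, grp, max))
        seg <- recompute(seg)
      }
    }
    width <- seg$end - seg$start
    small <- which(width < min_size)
    if (!length(small) || nrow(seg) == 1L) break
    k <- small[which.min(width[small])]
    nbr <- c(if (k > 1) k - 1L, if (k < nrow(seg)) k + 1L)
    d <- abs(seg$gc[nbr] - seg$gc[k])
    into <- nbr[which.min(d)]  # which.min takes the first (left) on ties
    seg$lo[into] <- min(seg$lo[into], seg$lo[k])
    seg$hi[into] <- max(seg$hi[into], seg$hi[k])
    seg <- seg[-k, , drop = FALSE]
    seg <- recompute(seg)
  }
  flag <- ifelse(seg$end - seg$start < min_size, "short", "")
  data.frame(start = seg$start, end = seg$end, mean_gc = seg$gc,
             family = .FAMILIES[seg$fam],
             n_windows = seg$hi - seg$lo + 1L, flag = flag)
}

#' CTCF site density per isochore family
#'
#' Each site is assigned to the unique isochore containing it (half-open
#' intervals); density is sites per Mb of the family's total span.
#' Sites falling in no isochore are tallied in an `"unassigned"` row
#' (with NA density).
#'
#' @param sites Data frame with columns `chrom`, `pos`.
#' @param isochores Data frame with `chrom`, `start`, `end`, `family`
#'   (disjoint intervals).
#' @return Data frame with columns `family`, `n_sites`, `mb`,
#'   `density_per_mb`.
#' @export
ctcf_density_by_family <- function(sites, isochores) {
  fam <- rep(NA_character_, nrow(sites))
  for (chrom in unique(sites$chrom)) {
    si <- which(sites$chrom == chrom)
    iso <- isochores[isochores$chrom == chrom, ]
    if (!nrow(iso)) next
    iso <- iso[order(iso$start), ]
    k <- findInterval(sites$pos[si], iso$start)
    ok <- k >= 1 & sites$pos[si] < iso$end[pmax(k, 1)]
    fam[si[ok]] <- iso$family[k[ok]]
  }
  mb <- vapply(.FAMILIES, function(f) {
    sum(isochores$end[isochores$family == f] -
          isochores$start[isochores$family == f]) / 1e6
  }, numeric(1))
  counts <- vapply(.FAMILIES, function(f) sum(fam == f, na.rm = TRUE),
                   numeric(1))
  out <- data.frame(family = .FAMILIES, n_sites = counts, mb = mb,
                    density_per_mb = ifelse(mb > 0, counts / mb, NA_real_))
  out <- rbind(out, data.frame(family = "unassigned",
                               n_sites = sum(is.na(fam)), mb = NA_real_,
                               density_per_mb = NA_real_))
  rownames(out) <- NULL
  out
}

#' Compare recovered isochores with planted truth
#'
#' Two recovery measures: the fraction of true internal boundaries with
#' a recovered boundary within `tolerance` bp, and the fraction of
#' genome bp whose recovered family label matches the truth.
#'
#' @param recovered Segmentation output (`chrom`, `start`, `end`,
#'   `family`).
#' @param truth_isochores Truth table (`chrom`, `start`, `end`,
#'   `family`).
#' @param genome Named vector of chromosome lengths.
#' @param tolerance Boundary match tolerance in bp (e.g. one window).
#' @return List with `boundary_recall`, `bp_accuracy`, `n_boundaries`.
#' @export
segmentation_accuracy <- function(recovered, truth_isochores, genome,
                                  tolerance) {
  matched <- 0L; total <- 0L; agree_bp <- 0; total_bp <- sum(genome)
  for (chrom in names(genome)) {
    tr <- truth_isochores[truth_isochores$chrom %in% chrom, ]
    rc <- recovered[recovered$chrom %in% chrom, ]
    tr <- tr[order(tr$start), ]; rc <- rc[order(rc$start), ]
    tb <- tr$end[-nrow(tr)]               # internal truth boundaries
    rb <- sort(unique(c(rc$start, rc$end)))
    if (length(tb) && length(rb)) {
      k <- findInterval(tb, rb)
      d_lo <- ifelse(k >= 1, tb - rb[pmax(k, 1)], Inf)
      d_hi <- ifelse(k < length(rb), rb[pmin(k + 1, length(rb))] - tb, Inf)
      matched <- matched + sum(pmin(d_lo, d_hi) <= tolerance)
    }
    total <- total + length(tb)
    if (!nrow(rc)) next
    # per-bp label agreement over elementary segments
    pts <- sort(unique(c(tr$start, tr$end, rc$start, rc$end)))
    if (length(pts) > 1) {
      lo <- pts[-length(pts)]; hi <- pts[-1]
      mid <- (lo + hi) / 2
      tf <- tr$family[findInterval(mid, tr$start)]
      ki <- findInterval(mid, rc$start)
      rf <- ifelse(ki >= 1 & mid < rc$end[pmax(ki, 1)],
                   rc$family[pmax(ki, 1)], NA_character_)
      agree_bp <- agree_bp + sum((hi - lo)[!is.na(rf) & rf == tf])
    }
  }
  list(boundary_recall = if (total) matched / total else NA_real_,
       bp_accuracy = agree_bp / total_bp,
       n_boundaries = total)
}
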