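# Binned contact matrices and isochore-class-stratified statistics.

#' Create a binned contact matrix
#'
#' Sparse symmetric container: `bins` is an ordered bin table tiling the
#' chromosome(s) at `resolution` (the last bin of a chromosome may be
#' short) and `values` holds the non-zero upper-triangle entries. Input
#' values listing both `(i, j)` and `(j, i)` are accepted when
#' consistent and canonicalised to `i <= j`.
#'
#' @param bins Data frame `bin_id`, `chrom`, `start`, `end`.
#' @param values Data frame `bin_i`, `bin_j`, `value` (non-negative).
#' @param resolution Bin size in bp.
#' @param kind `"intra"` or `"inter"`.
#' @param normalization_tag Free-text provenance of any upstream matrix
#'   normalization (matrices are consumed pre-normalized).
#' @param genome Optional named chromosome lengths.
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, values, resolution,
                           kind = c("intra", "inter"),
                           normalization_tag = "unknown", genome = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(c("bin_id", "chrom", "start", "end") %in% names(bins)),
            all(c("bin_i", "bin_j", "value") %in% names(values)))
  if (any(values$value < 0)) stop("contact values must be non-negative")
  if (!all(values$bin_i %in% bins$bin_id) ||
      !all(values$bin_j %in% bins$bin_id))
    stop("values reference unknown bin ids")
  # bins must tile each chromosome at the declared resolution
  for (chrom in unique(bins$chrom)) {
    b <- bins[bins$chrom == chrom, ]
    b <- b[order(b$start), ]
    if (any(b$start != (seq_len(nrow(b)) - 1) * resolution) ||
        any(utils::head(b$end, -1) != utils::head(b$start, -1) + resolution))
      stop("bin tiling of ", chrom, " inconsistent with resolution ",
           resolution)
  }
  # canonicalise to upper triangle, checking symmetry of duplicates
  i <- pmin(values$bin_i, values$bin_j)
  j <- pmax(values$bin_i, values$bin_j)
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    chk <- tapply(values$value, key, function(v) length(unique(v)) == 1L)
    if (!all(chk)) {
      bad <- names(chk)[!chk][1]
      stop("asymmetric value for bin pair (", sub(" ", ", ", bad), ")")
    }
    keep <- !duplicated(key)
    i <- i[keep]; j <- j[keep]
    v <- values$value[keep]
  } else v <- values$value
  o <- order(i, j)
  structure(list(resolution = resolution,
                 bins = bins[order(bins$bin_id), ],
                 values = data.frame(bin_i = i[o], bin_j = j[o],
                                     value = v[o]),
                 kind = kind, normalization_tag = normalization_tag,
                 genome = genome),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix>", x$kind, "|", nrow(x$bins), "bins at",
      format(x$resolution, big.mark = ","), "bp |", nrow(x$values),
      "non-zero entries |", x$normalization_tag, "\n")
  invisible(x)
}

#' Read / write a contact matrix as bin-table + triplet TSV
#'
#' @param mat A [contact_matrix()].
#' @param bins_path Path of the bin table TSV (`bin_id`, `chrom`,
#'   `start`, `end`).
#' @param triplets_path Path of the triplet TSV (`bin_i`, `bin_j`,
#'   `value`).
#' @param resolution,kind,normalization_tag Passed to
#'   [contact_matrix()] when reading.
#' @return `read_contact_matrix` returns a `contact_matrix`;
#'   `write_contact_matrix` returns the paths invisibly.
#' @export
write_contact_matrix <- function(mat, bins_path, triplets_path) {
  utils::write.table(mat$bins, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(mat$values, triplets_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bins_path, triplets_path))
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(bins_path, triplets_path, resolution,
                                kind = c("intra", "inter"),
                                normalization_tag = "unknown") {
  bins <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  values <- utils::read.table(triplets_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  contact_matrix(bins, values, resolution, kind, normalization_tag)
}

# Majority-overlap family assignment for arbitrary intervals.
# Returns the family per interval, or NA when covered < min_cover.
.majority_family <- function(intervals, isochores, min_cover = 0.5) {
  fam <- rep(NA_character_, nrow(intervals))
  for (chrom in unique(intervals$chrom)) {
    rows <- which(intervals$chrom == chrom)
    iso <- isochores[isochores$chrom == chrom, ]
    if (!nrow(iso)) next
    iso <- iso[order(iso$start), ]
    for (r in rows) {
      s <- intervals$start[r]; e <- intervals$end[r]
      ii <- which(iso$end > s & iso$start < e)
      if (!length(ii)) next
      ov <- pmin(iso$end[ii], e) - pmax(iso$start[ii], s)
      if (sum(ov) < min_cover * (e - s)) next
      by_fam <- tapply(ov, iso$family[ii], sum)
      top <- names(by_fam)[by_fam == max(by_fam)]
      if (length(top) == 1L) fam[r] <- top
      else {
        # exact tie: family of the isochore containing the midpoint
        mid <- (s + e) / 2
        k <- findInterval(mid, iso$start)
        fam[r] <- if (k >= 1 && mid < iso$end[k]) iso$family[k] else top[1]
      }
    }
  }
  fam
}

#' Annotate contact-matrix bins with isochore families
#'
#' Each bin gets the family of the majority of its overlap with the
#' isochore set; an exact tie goes to the family of the isochore
#' containing the bin midpoint; bins covered over less than half their
#' length are unassigned. The class groups H1/H2/H3 as GC-rich and
#' L1/L2 as GC-poor.
#'
#' @param x A `contact_matrix` or a bin table data frame.
#' @param isochores Isochore table (`chrom`, `start`, `end`, `family`).
#' @return Data frame `bin_id`, `chrom`, `start`, `end`, `family`,
#'   `class` (`GC-rich` / `GC-poor` / `unassigned`).
#' @export
annotate_bins <- function(x, isochores) {
  bins <- if (inherits(x, "contact_matrix")) x$bins else x
  fam <- .majority_family(bins, isochores)
  data.frame(bin_id = bins$bin_id, chrom = bins$chrom,
             start = bins$start, end = bins$end,
             family = ifelse(is.na(fam), "unassigned", fam),
             class = .family_class(fam))
}

#' Class-stratified mean contact profile
#'
#' Every unordered pair of distinct annotated bins on the same
#' chromosome contributes once to its (class pair, distance stratum)
#' cell; unassigned bins are excluded and absent sparse entries count as
#' zeros. Distance is the separation of bin starts in bp.
#'
#' @param mat An intra-chromosomal `contact_matrix`.
#' @param annotation Output of [annotate_bins()].
#' @param distance_breaks Increasing bp breakpoints defining the strata
#'   (distances above the last break form the final stratum).
#' @return Data frame `class_i`, `class_j`, `stratum` (label),
#'   `dist_lo`, `dist_hi`, `n_pairs`, `mean_value`.
#' @export
stratified_contact_profile <- function(mat, annotation, distance_breaks) {
  stopifnot(inherits(mat, "contact_matrix"),
            all(diff(distance_breaks) > 0))
  ann <- annotation[annotation$class != "unassigned", ]
  pieces <- list()
  for (chrom in unique(ann$chrom)) {
    a <- ann[ann$chrom == chrom, ]
    a <- a[order(a$start), ]
    n <- nrow(a)
    if (n < 2) next
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L) + i
    d <- a$start[j] - a$start[i]
    key_all <- paste(pmin(a$bin_id[i], a$bin_id[j]),
                     pmax(a$bin_id[i], a$bin_id[j]))
    v <- mat$values$value[match(key_all,
                                paste(mat$values$bin_i, mat$values$bin_j))]
    v[is.na(v)] <- 0
    ci <- pmin(a$class[i], a$class[j])
    cj <- pmax(a$class[i], a$class[j])
    stratum <- findInterval(d, distance_breaks)
    pieces[[length(pieces) + 1L]] <-
      data.frame(ci = ci, cj = cj, stratum = stratum, v = v)
  }
  if (!length(pieces))
    return(data.frame(class_i = character(0), class_j = character(0),
                      stratum = character(0), dist_lo = numeric(0),
                      dist_hi = numeric(0), n_pairs = integer(0),
                      mean_value = numeric(0)))
  all_p <- do.call(rbind, pieces)
  agg_n <- stats::aggregate(v ~ ci + cj + stratum, all_p, length)
  agg_m <- stats::aggregate(v ~ ci + cj + stratum, all_p, mean)
  lo <- c(0, distance_breaks)
  hi <- c(distance_breaks, Inf)
  out <- data.frame(class_i = agg_n$ci, class_j = agg_n$cj,
                    stratum = sprintf("(%g,%g]", lo[agg_n$stratum + 1],
                                      hi[agg_n$stratum + 1]),
                    dist_lo = lo[agg_n$stratum + 1],
                    dist_hi = hi[agg_n$stratum + 1],
                    n_pairs = agg_n$v, mean_value = agg_m$v)
  out[order(out$class_i, out$class_j, out$dist_lo), ]
}

#' Ratio of GC-poor to GC-rich long-range contact intensity
#'
#' Compares mean GC-poor/GC-poor and GC-rich/GC-rich contact values at
#' matched bin distances beyond `min_dist`, averaging the per-distance
#' means with equal weight over the distances present in both classes.
#' On synthetic matrices this recovers the planted GC-poor long-range
#' boost.
#'
#' @param mat An intra-chromosomal `contact_matrix`.
#' @param annotation Output of [annotate_bins()].
#' @param min_dist Minimum bp distance defining "long range"
#'   (default 5 Mb).
#' @return The intensity ratio (GC-poor over GC-rich).
#' @export
gcpoor_longrange_ratio <- function(mat, annotation, min_dist = 5e6) {
  res <- mat$resolution
  dmax <- max(annotation$start)
  breaks <- seq(res, dmax + res, by = res)
  prof <- stratified_contact_profile(mat, annotation, breaks)
  prof <- prof[prof$dist_lo >= min_dist, ]
  pp <- prof[prof$class_i == "GC-poor" & prof$class_j == "GC-poor", ]
  rr <- prof[prof$class_i == "GC-rich" & prof$class_j == "GC-rich", ]
  common <- intersect(pp$dist_lo, rr$dist_lo)
  if (!length(common)) return(NA_real_)
  sum(pp$mean_value[match(common, pp$dist_lo)]) /
    sum(rr$mean_value[match(common, rr$dist_lo)])
}

#' Fit the contact distance-decay exponent
#'
#' Log-log regression of the mean contact value on bin distance over
#' GC-rich/GC-rich pairs (which carry no GC-poor boost) between
#' `min_dist` and `max_dist`. Returns the positive decay exponent.
#'
#' @param mat An intra-chromosomal `contact_matrix`.
#' @param annotation Output of [annotate_bins()].
#' @param min_dist,max_dist Distance window in bp for the fit.
#' @return Estimated decay exponent (positive).
#' @export
fit_decay_exponent <- function(mat, annotation, min_dist = NULL,
                               max_dist = NULL) {
  res <- mat$resolution
  min_dist <- min_dist %||% res
  max_dist <- max_dist %||% (max(annotation$start) / 2)
  dmax <- max(annotation$start)
  prof <- stratified_contact_profile(mat, annotation,
                                     seq(res, dmax + res, by = res))
  rr <- prof[prof$class_i == "GC-rich" & prof$class_j == "GC-rich" &
               prof$dist_lo >= min_dist & prof$dist_lo <= max_dist &
               prof$mean_value > 0, ]
  if (nrow(rr) < 3) stop("too few distance strata for a decay fit")
  fit <- stats::lm(log(mean_value) ~ log(dist_lo), data = rr,
                   weights = rr$n_pairs)
  -unname(stats::coef(fit)[2])
}

#' Largest inter-chromosomal interactions
#'
#' The `n` largest off-diagonal entries of an inter-chromosomal matrix,
#' sorted by decreasing value with ties broken by ascending
#' `(bin_i, bin_j)`. Requesting more than the stored non-zero entries
#' returns them all with a warning.
#'
#' @param mat An inter-chromosomal `contact_matrix`.
#' @param n Number of interactions to return.
#' @return Data frame `bin_i`, `bin_j`, `value`, `chrom_i`, `start_i`,
#'   `chrom_j`, `start_j`.
#' @export
top_interactions <- function(mat, n = 100L) {
  stopifnot(inherits(mat, "contact_matrix"), n >= 1)
  if (mat$kind != "inter")
    stop("top_interactions is defined for inter-chromosomal matrices")
  v <- mat$values[mat$values$value > 0 &
                    mat$values$bin_i != mat$values$bin_j, ]
  if (nrow(v) < n) {
    warning("only ", nrow(v), " non-zero entries available (requested ",
            n, ")")
    n <- nrow(v)
  }
  v <- v[order(-v$value, v$bin_i, v$bin_j), ][seq_len(n), , drop = FALSE]
  bi <- match(v$bin_i, mat$bins$bin_id)
  bj <- match(v$bin_j, mat$bins$bin_id)
  out <- data.frame(bin_i = v$bin_i, bin_j = v$bin_j, value = v$value,
                    chrom_i = mat$bins$chrom[bi],
                    start_i = mat$bins$start[bi],
                    chrom_j = mat$bins$chrom[bj],
                    start_j = mat$bins$start[bj])
  rownames(out) <- NULL
  out
}

#' Class composition of bins involved in top interactions
#'
#' Over the distinct annotated bins participating in the supplied top
#' interactions (a bin appearing in many pairs counts once, keyed by
#' chromosome and start), the fraction belonging to the GC-rich and
#' GC-poor classes; the two fractions sum to one over assigned bins.
#'
#' @param tops Data frame of top interactions (concatenated over
#'   chromosome pairs) with columns `chrom_i`, `start_i`, `chrom_j`,
#'   `start_j`, as returned by [top_interactions()].
#' @param annotation Genome-wide bin annotation from [annotate_bins()].
#' @return List `frac_gc_rich`, `frac_gc_poor`, `n_bins`,
#'   `n_unassigned`.
#' @export
interaction_class_fractions <- function(tops, annotation) {
  keys <- unique(c(paste(tops$chrom_i, tops$start_i),
                   paste(tops$chrom_j, tops$start_j)))
  cls <- annotation$class[match(keys, paste(annotation$chrom,
                                            annotation$start))]
  assigned <- cls[!is.na(cls) & cls != "unassigned"]
  n <- length(assigned)
  list(frac_gc_rich = if (n) mean(assigned == "GC-rich") else NA_real_,
       frac_gc_poor = if (n) mean(assigned == "GC-poor") else NA_real_,
       n_bins = n,
       n_unassigned = length(keys) - n)
}

#' Boundary concordance between domains and isochores
#'
#' Fraction of domain boundaries (starts and ends) lying within
#' `tolerance` bp of the nearest isochore boundary on the same
#' chromosome. Domains on chromosomes without isochores count as
#' unmatched.
#'
#' @param domains Domain table or `region_set` (`chrom`, `start`,
#'   `end`).
#' @param isochores Isochore table (`chrom`, `start`, `end`).
#' @param tolerance Match tolerance in bp (>= 0).
#' @return List `fraction`, `n_matched`, `n_total`.
#' @export
boundary_concordance <- function(domains, isochores, tolerance) {
  stopifnot(tolerance >= 0)
  if (inherits(domains, "region_set")) domains <- domains$regions
  matched <- 0L; total <- 0L
  for (chrom in unique(domains$chrom)) {
    db <- sort(c(domains$start[domains$chrom == chrom],
                 domains$end[domains$chrom == chrom]))
    total <- total + length(db)
    iso <- isochores[isochores$chrom == chrom, ]
    if (!nrow(iso)) next
    ib <- sort(unique(c(iso$start, iso$end)))
    k <- findInterval(db, ib)
    d_lo <- ifelse(k >= 1, db - ib[pmax(k, 1)], Inf)
    d_hi <- ifelse(k < length(ib), ib[pmin(k + 1, length(ib))] - db, Inf)
    matched <- matched + sum(pmin(d_lo, d_hi) <= tolerance)
  }
  list(fraction = if (total) matched / total else NA_real_,
       n_matched = matched, n_total = total)
}

#' Lamina contact frequency summaries per isochore family
#'
#' LADs are assigned to isochore families by majority overlap (the same
#' rule as [annotate_bins()]); per family the table reports the LAD
#' count, mean contact frequency and the fraction of LADs above the
#' high-CF threshold (default 0.8, i.e. lamina contact in over 80% of
#' cells).
#'
#' @param lads Data frame `chrom`, `start`, `end`, `cf` with CF in
#'   `[0, 1]`.
#' @param isochores Isochore table.
#' @param cf_threshold High-CF threshold (default 0.8).
#' @return Data frame `family`, `n`, `mean_cf`, `frac_high_cf`, one row
#'   per family with at least one LAD.
#' @export
lad_cf_by_family <- function(lads, isochores, cf_threshold = 0.8) {
  if (!nrow(lads))
    return(data.frame(family = character(0), n = integer(0),
                      mean_cf = numeric(0), frac_high_cf = numeric(0)))
  if (any(lads$cf < 0 | lads$cf > 1))
    stop("contact frequencies must lie in [0, 1]")
  fam <- .majority_family(lads, isochores)
  ok <- !is.na(fam)
  if (!any(ok))
    return(data.frame(family = character(0), n = integer(0),
                      mean_cf = numeric(0), frac_high_cf = numeric(0)))
  spl <- split(lads$cf[ok], fam[ok])
  out <- data.frame(family = names(spl),
                    n = vapply(spl, length, integer(1)),
                    mean_cf = vapply(spl, mean, numeric(1)),
                    frac_high_cf = vapply(spl, function(v)
                      mean(v > cf_threshold), numeric(1)))
  out <- out[order(match(out$family, .FAMILIES)), ]
  rownames(out) <- NULL
  out
}
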