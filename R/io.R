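# File input/output: FASTA via Biostrings, BED via rtracklayer, plain
# TSVs for genome tables and GC profiles. All coordinates on disk are
# 0-based half-open (BED convention).

#' Write a genome to FASTA
#'
#' One record per chromosome, wrapped at 80 columns.
#'
#' @param sequences A [Biostrings::DNAStringSet] (named by chromosome).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path, width = 80L)
  invisible(path)
}

#' Read / write a chromosome length table
#'
#' Two-column TSV (`chrom`, `length`), no header.
#'
#' @param genome Named numeric vector of chromosome lengths.
#' @param path File path.
#' @return `read_genome` returns a named numeric vector.
#' @export
write_genome <- function(genome, path) {
  utils::write.table(data.frame(chrom = names(genome),
                                length = as.numeric(genome)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  g <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "length"),
                         stringsAsFactors = FALSE)
  stats::setNames(g$length, g$chrom)
}

#' Read a BED file as a 0-based half-open interval data frame
#'
#' @param path BED file path (3 to 6 columns).
#' @return Data frame `chrom`, `start`, `end`, plus `name` / `score`
#'   when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(mc)) out$name <- mc$name
  if ("score" %in% names(mc) && !all(is.na(mc$score))) out$score <- mc$score
  out
}

#' Write intervals to BED
#'
#' @param df Data frame with `chrom`, `start`, `end` (0-based
#'   half-open); optional columns selected by `name_col` / `score_col`
#'   become BED columns 4 and 5.
#' @param path Output path.
#' @param name_col,score_col Optional column names.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, name_col = NULL, score_col = NULL) {
  if (inherits(df, "region_set")) df <- df$regions
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(start = df$start + 1,
                                                end = df$end))
  if (!is.null(name_col)) gr$name <- as.character(df[[name_col]])
  if (!is.null(score_col)) {
    if (is.null(name_col)) gr$name <- "."
    gr$score <- df[[score_col]]
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write true or segmented isochores as BED5
#'
#' Column 4 holds the family, column 5 the GC rounded to one decimal
#' times ten (so 43.7% GC scores 437).
#'
#' @param isochores Isochore table with `family` and `gc` or `mean_gc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isochore_bed <- function(isochores, path) {
  gc_col <- if ("gc" %in% names(isochores)) "gc" else "mean_gc"
  df <- isochores
  df$score <- round(10 * df[[gc_col]])
  write_bed(df, path, name_col = "family", score_col = "score")
}

#' Write a GC profile as TSV
#'
#' Columns `chrom`, `start`, `end`, `gc` (NA for masked windows).
#'
#' @param profile A `gc_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gc_profile <- function(profile, path) {
  utils::write.table(data.frame(chrom = attr(profile, "chrom"),
                                start = profile$start, end = profile$end,
                                gc = profile$gc),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
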