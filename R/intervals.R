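#' Intervals on contig or element coordinates
#'
#' The package reports coordinates 1-based, with intervals half-open on the
#' right: an interval `(start, end)` covers bases `start .. end - 1` and its
#' length is `end - start`. This convention is chosen so that printed interval
#' arithmetic such as `15648 - 10098 = 5550` holds by plain subtraction.
#' Conversions to the inclusive GFF3 convention (`end - 1`) and the 0-based
#' half-open BED convention (`start - 1`, `end - 1`) are handled by the
#' writers, never by callers.
#'
#' @param start 1-based start position (first base of the interval).
#' @param end End position; the interval covers `start .. end - 1`.
#' @param strand `"+"` or `"-"`.
#' @return A list with elements `start`, `end`, `strand` of class
#'   `"cacta_interval"`.
#' @examples
#' iv <- interval(10098, 15648)
#' interval_length(iv)  # 5550
#' @export
interval <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("interval bounds must be integers")
  if (end < start) stop("interval end must be >= start")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(start = start, end = end, strand = strand),
            class = "cacta_interval")
}

#' Length of an interval
#'
#' @param iv An [interval()].
#' @return `end - start`, in bp.
#' @export
interval_length <- function(iv) {
  iv <- as_interval(iv)
  iv$end - iv$start
}

#' @noRd
as_interval <- function(x) {
  if (inherits(x, "cacta_interval")) return(x)
  if (is.list(x) && all(c("start", "end") %in% names(x)))
    return(interval(x$start, x$end, if (is.null(x$strand)) "+" else x$strand))
  if (is.numeric(x) && length(x) >= 2L)
    return(interval(x[[1L]], x[[2L]]))
  stop("cannot interpret object as an interval")
}

#' @noRd
iv_overlaps <- function(a, b) {
  a <- as_interval(a); b <- as_interval(b)
  a$start < b$end && b$start < a$end
}

#' @noRd
iv_contains <- function(outer, inner) {
  outer <- as_interval(outer); inner <- as_interval(inner)
  inner$start >= outer$start && inner$end <= outer$end
}

#' @noRd
iv_shift <- function(iv, by) {
  iv <- as_interval(iv)
  interval(iv$start + by, iv$end + by, iv$strand)
}

#' Intervals as a data frame
#'
#' @param ivs A list of [interval()]s (or a single one).
#' @return data.frame with columns `start`, `end`, `strand`, `length`.
#' @export
intervals_df <- function(ivs) {
  if (inherits(ivs, "cacta_interval")) ivs <- list(ivs)
  if (length(ivs) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length = integer()))
  ivs <- lapply(ivs, as_interval)
  data.frame(
    start  = vapply(ivs, `[[`, integer(1), "start"),
    end    = vapply(ivs, `[[`, integer(1), "end"),
    strand = vapply(ivs, `[[`, character(1), "strand"),
    length = vapply(ivs, interval_length, integer(1))
  )
}

#' Write features to GFF3
#'
#' Converts the package's half-open 1-based intervals to GFF3's inclusive
#' 1-based coordinates (`end - 1`). Zero-length intervals are not written.
#'
#' @param features data.frame with columns `seqid`, `source`, `type`, `start`,
#'   `end` (half-open), `score`, `strand`, `phase`, `attributes`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    keep <- features$end > features$start
    features <- features[keep, , drop = FALSE]
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     features$seqid, features$source, features$type,
                     as.integer(features$start),
                     as.integer(features$end) - 1L,
                     features$score, features$strand, features$phase,
                     features$attributes)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write intervals to BED (0-based half-open)
#'
#' @param seqid Contig name (recycled).
#' @param ivs List of intervals.
#' @param names Feature names.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(seqid, ivs, names, path) {
  df <- intervals_df(ivs)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   rep_len(seqid, nrow(df)), df$start - 1L, df$end - 1L,
                   rep_len(names, nrow(df)), df$strand)
  writeLines(lines, path)
  invisible(path)
}
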