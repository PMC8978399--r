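# Protein-domain hit ingestion, filtering, ORF assignment and
# conserved-domain-architecture (CDA) typing.

CANONICAL_DOMAINS <- c("TAD", "Transposase_21", "DUF4218", "DUF4216",
                       "Transposase_24", "Peptidase_C48")

#' @noRd
canonicalize_domain <- function(name) {
  ifelse(name %in% CANONICAL_DOMAINS, name, paste0("other:", name))
}

#' Load a protein-domain hit table
#'
#' Two dialects modeled on DANTE output are supported: a GFF3 whose
#' attributes carry `Name`, `Identity`, `Similarity`, `Relat_Length`,
#' `Interruptions` (and optionally `Length_Proportion`), and a flat TSV with
#' columns `seqid`, `name`, `start`, `end`, `strand`, `identity`,
#' `similarity`, `aln_len_prop`, `interruptions`, `length_prop`. File
#' coordinates are 1-based inclusive (the GFF3 convention) and are converted
#' to the package's half-open intervals on ingest. Domain names outside the
#' six canonical CACTA domains are mapped to `other:<label>`.
#'
#' @param path Path to the hit table.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return data.frame with columns `seqid`, `name`, `start`, `end` (half-open),
#'   `strand`, `identity`, `similarity`, `aln_len_prop`, `interruptions`,
#'   `length_prop`.
#' @export
load_domain_hits <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("hit table not found: ", path)
  if (dialect == "tsv") {
    if (length(readLines(path, n = 1L)) == 0L) return(empty_hits())
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("seqid", "name", "start", "end", "strand", "identity",
             "similarity", "aln_len_prop", "interruptions", "length_prop")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("hit table is missing required column(s): ",
           paste(miss, collapse = ", "))
    if (nrow(df) == 0L) return(empty_hits())
    hits <- df[req]
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) == 0L) return(empty_hits())
    md <- S4Vectors::mcols(gr)
    need <- c("Name", "Identity", "Similarity", "Relat_Length", "Interruptions")
    miss <- setdiff(need, names(md))
    if (length(miss))
      stop("GFF3 hit table is missing required attribute(s): ",
           paste(miss, collapse = ", "))
    lp <- if ("Length_Proportion" %in% names(md))
      as.numeric(as.character(md$Length_Proportion)) else rep(1, length(gr))
    hits <- data.frame(
      seqid = as.character(GenomicRanges::seqnames(gr)),
      name = as.character(md$Name),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
      identity = as.numeric(as.character(md$Identity)),
      similarity = as.numeric(as.character(md$Similarity)),
      aln_len_prop = as.numeric(as.character(md$Relat_Length)),
      interruptions = as.integer(as.character(md$Interruptions)),
      length_prop = lp,
      stringsAsFactors = FALSE)
  }
  hits$name <- canonicalize_domain(hits$name)
  hits$end <- as.integer(hits$end) + 1L  # inclusive file coords -> half-open
  hits$start <- as.integer(hits$start)
  rownames(hits) <- NULL
  hits
}

#' @noRd
empty_hits <- function() {
  data.frame(seqid = character(), name = character(), start = integer(),
             end = integer(), strand = character(), identity = numeric(),
             similarity = numeric(), aln_len_prop = numeric(),
             interruptions = integer(), length_prop = numeric())
}

#' Filter domain hits with DANTE-style quality thresholds
#'
#' A hit is kept only when all five conditions hold simultaneously:
#' identity and similarity at or above their minima, relative alignment
#' length at or above its minimum, no more interruptions (frameshifts plus
#' stop codons) than allowed, and length proportion at or below its maximum.
#' The defaults are the thresholds commonly used for transposase-domain
#' filtering. Order is preserved; the operation is idempotent.
#'
#' @param hits data.frame from [load_domain_hits()].
#' @param min_identity,min_similarity,min_aln_len,max_interruptions,max_len_prop
#'   Filter thresholds.
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, min_identity = 0.35, min_similarity = 0.45,
                        min_aln_len = 0.8, max_interruptions = 0L,
                        max_len_prop = 1.2) {
  keep <- hits$identity >= min_identity &
    hits$similarity >= min_similarity &
    hits$aln_len_prop >= min_aln_len &
    hits$interruptions <= max_interruptions &
    hits$length_prop <= max_len_prop
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select full-length tnp2 (Transposase_21) hits
#'
#' The complete tnp2 domain is about 630 bp at the nucleotide level; hits of
#' the Transposase_21 family whose length falls within
#' `target_len * (1 - tolerance)` and `target_len * (1 + tolerance)`
#' (closed interval) are considered full length, the rest remnants.
#'
#' @param hits data.frame of domain hits.
#' @param target_len Nominal full-length size in bp.
#' @param tolerance Symmetric relative tolerance in `[0, 1)`.
#' @return The full-length Transposase_21 rows of `hits`.
#' @export
select_full_length_tnp2 <- function(hits, target_len = 630L, tolerance = 0.1) {
  if (tolerance < 0 || tolerance >= 1) stop("tolerance must be in [0, 1)")
  len <- hits$end - hits$start
  keep <- hits$name == "Transposase_21" &
    len >= target_len * (1 - tolerance) &
    len <= target_len * (1 + tolerance)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign domain hits to ORF1 / ORF2
#'
#' ORF1 is operationally the coding interval that holds the Transposase_21
#' hit; hits contained in it are labeled ORF1, all others ORF2. A hit
#' straddling a coding boundary is assigned by its midpoint and flagged.
#' Domains are stored on the element in positional order.
#'
#' @param element An element model from [call_element()].
#' @param coding_ivs List of coding-sequence [interval()]s in element
#'   coordinates.
#' @param hits data.frame of domain hits in element coordinates.
#' @return The element with `domains` (hits plus `orf` and `straddles`
#'   columns) and `coding_ivs` filled in.
#' @export
assign_orfs <- function(element, coding_ivs, hits) {
  tp <- which(hits$name == "Transposase_21")
  if (length(tp) == 0L)
    stop("no Transposase_21 hit; element is not classifiable")
  tp_iv <- interval(hits$start[tp[1L]], hits$end[tp[1L]])
  orf1 <- NULL
  for (civ in coding_ivs) {
    if (iv_overlaps(civ, tp_iv)) { orf1 <- as_interval(civ); break }
  }
  if (is.null(orf1))
    stop("no coding interval contains the Transposase_21 hit")
  n <- nrow(hits)
  orf <- character(n); straddles <- logical(n)
  for (i in seq_len(n)) {
    hiv <- interval(hits$start[i], hits$end[i])
    inside <- iv_contains(orf1, hiv)
    overlaps <- iv_overlaps(orf1, hiv)
    if (inside) {
      orf[i] <- "ORF1"
    } else if (overlaps) {
      mid <- (hits$start[i] + hits$end[i]) / 2
      orf[i] <- if (mid >= orf1$start && mid < orf1$end) "ORF1" else "ORF2"
      straddles[i] <- TRUE
    } else {
      orf[i] <- "ORF2"
    }
  }
  hits$orf <- orf
  hits$straddles <- straddles
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  element$domains <- hits
  element$coding_ivs <- lapply(coding_ivs, as_interval)
  element
}

#' Classify the conserved domain architecture (CDA)
#'
#' The four CDA types of CACTA-like elements, judged on the ordered list of
#' canonical domain names along the element's sense strand:
#' * `type1`: TAD, Transposase_21, DUF4218, DUF4216 (the basic ORF1 set);
#' * `type2`: basic set plus Peptidase_C48;
#' * `type3`: basic set plus Transposase_24;
#' * `type4`: basic set plus Transposase_24 followed by Peptidase_C48.
#'
#' Any other multiset -- a missing basic domain, an extra domain, a
#' non-canonical name -- or any out-of-order arrangement of a canonical
#' multiset classifies as `other` (with a warning for the out-of-order
#' case), recording the observed basis.
#'
#' @param domains_in_order Character vector of domain names, in positional
#'   order.
#' @return List with `label` (`"type1"`..`"type4"` or `"other"`) and `basis`
#'   (the input order).
#' @export
classify_cda <- function(domains_in_order) {
  if (length(domains_in_order) == 0L) stop("empty domain list")
  basic <- c("TAD", "Transposase_21", "DUF4218", "DUF4216")
  patterns <- list(
    type1 = basic,
    type2 = c(basic, "Peptidase_C48"),
    type3 = c(basic, "Transposase_24"),
    type4 = c(basic, "Transposase_24", "Peptidase_C48"))
  label <- "other"
  for (ty in names(patterns)) {
    if (identical(unname(domains_in_order), patterns[[ty]])) { label <- ty; break }
  }
  if (label == "other") {
    for (ty in names(patterns)) {
      if (identical(sort(domains_in_order), sort(patterns[[ty]]))) {
        warning("canonical CDA multiset in non-canonical order; ",
                "classifying as 'other'")
        break
      }
    }
  }
  list(label = label, basis = as.character(domains_in_order))
}
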