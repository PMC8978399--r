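# Captured gene fragments relative to element landmarks, and tandem
# satellite-DNA arrays inside elements.

#' Annotate captured gene fragments relative to the TAD landmark
#'
#' Captured host-gene fragments of CACTA elements sit in the 5' region
#' upstream of the TAD domain; their position is conventionally reported as
#' the intervening distance between the fragment and the TAD start
#' (`dist_to_tad = TAD start - fragment end`, positive when the fragment is
#' upstream).
#'
#' @param element Element model with `domains` assigned (must include a TAD
#'   hit) and `coding_ivs` set.
#' @param fragment_hits data.frame with columns `label`, `start`, `end`
#'   (half-open element coordinates).
#' @return data.frame with columns `label`, `start`, `end`, `dist_to_tad`,
#'   `in_coding`, `element_region` (`"five_prime"`, `"internal"`,
#'   `"three_prime"`).
#' @export
annotate_capture <- function(element, fragment_hits) {
  if (is.null(element$domains) || !"TAD" %in% element$domains$name)
    stop("element lacks the TAD landmark; cannot place captured fragments")
  tad_start <- element$domains$start[element$domains$name == "TAD"][1L]
  coding <- lapply(element$coding_ivs, as_interval)
  cod_min <- if (length(coding)) min(vapply(coding, `[[`, integer(1), "start")) else NA
  cod_max <- if (length(coding)) max(vapply(coding, `[[`, integer(1), "end")) else NA
  n <- nrow(fragment_hits)
  out <- fragment_hits[, c("label", "start", "end"), drop = FALSE]
  out$dist_to_tad <- tad_start - fragment_hits$end
  out$in_coding <- vapply(seq_len(n), function(i) {
    iv <- interval(fragment_hits$start[i], fragment_hits$end[i])
    any(vapply(coding, iv_overlaps, logical(1), b = iv))
  }, logical(1))
  out$element_region <- vapply(seq_len(n), function(i) {
    if (out$in_coding[i]) return("internal")
    if (!is.na(cod_min) && fragment_hits$end[i] <= cod_min) return("five_prime")
    if (!is.na(cod_max) && fragment_hits$start[i] >= cod_max) return("three_prime")
    "internal"
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Per-column majority-rule consensus of equal-length copies
#'
#' Ties are broken by fixed base order `A < C < G < T` (then `N`), so the
#' consensus is deterministic.
#'
#' @param copies Character vector of equal-length DNA strings.
#' @return The consensus string.
#' @export
build_monomer_consensus <- function(copies) {
  if (length(copies) == 0L) stop("no copies given")
  lens <- nchar(copies)
  if (length(unique(lens)) != 1L) stop("copies differ in length")
  mat <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  order_bases <- c("A", "C", "G", "T", "N")
  cols <- apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = order_bases))
    order_bases[which.max(tab)]  # which.max returns the first (A<C<G<T<N) tie
  })
  paste(cols, collapse = "")
}

#' Detect tandem satellite arrays by shifted self-identity
#'
#' For each candidate monomer length the lag-p self-match profile is
#' summarized by its best rolling mean (window `2p`); periods reaching
#' `min_copy_identity` seed candidate arrays. The best period is reduced to
#' its smallest divisor scoring within 0.05 (a raw shifted-identity score
#' cannot distinguish a period from its harmonics under noise). Around the
#' profile peak, monomer copies are phased by best support, a majority-rule
#' consensus is built, and each array boundary is then placed where the
#' matches-minus-mismatches score of the sequence against the periodic
#' continuation of the consensus is maximal (mismatches weighted double, so
#' excursions into unrelated flank decay quickly). This finds a mid-copy
#' truncation point exactly on clean arrays and makes fractional copy
#' numbers well-defined. Candidate regions -- including degenerate or
#' sub-periodic ones -- are masked and the search repeats, so multiple
#' arrays per sequence are reported.
#'
#' The minimum monomer length of 30 bp deliberately excludes subTIR units
#' (10-20 bp) so termini are not double-annotated.
#'
#' @param s DNA string.
#' @param min_monomer,max_monomer Monomer length search range, bp.
#' @param min_copies Minimum (fractional) copies for a reported array.
#' @param min_copy_identity Minimum identity of a copy to the consensus.
#' @return List of arrays, each a list with `iv` ([interval()]),
#'   `monomer_len`, `consensus`, `copy_number` (one decimal, half-up),
#'   `mean_copy_identity`. Empty list when nothing is found.
#' @export
detect_tandem_array <- function(s, min_monomer = 30L, max_monomer = 400L,
                                min_copies = 3.0, min_copy_identity = 0.7) {
  check_dna(s)
  L <- nchar(s)
  if (L < min_monomer * min_copies)
    stop("sequence shorter than min_monomer * min_copies")
  x <- s2c(s)
  arrays <- list()
  for (round in 1:20) {
    found <- find_one_array(x, min_monomer, max_monomer, min_copies,
                            min_copy_identity)
    if (is.null(found)) break
    if (isTRUE(found$accept)) arrays[[length(arrays) + 1L]] <- found$array
    x[found$iv$start:(found$iv$end - 1L)] <- "#"  # mask; matches nothing
  }
  ord <- order(vapply(arrays, function(a) a$iv$start, integer(1)))
  arrays[ord]
}

#' @noRd
find_one_array <- function(x, min_monomer, max_monomer, min_copies,
                           min_copy_identity) {
  L <- length(x)
  pid <- function(a, b) {                    # mask-safe ungapped identity
    if (grepl("#", a, fixed = TRUE)) return(0)
    ungapped_identity(a, b)
  }
  ps <- seq(as.integer(min_monomer), as.integer(max_monomer))
  ps <- ps[2L * ps <= L]
  if (length(ps) == 0L) return(NULL)
  score <- rep(-Inf, length(ps))
  for (k in seq_along(ps)) {
    p <- ps[k]
    m <- as.numeric(x[1:(L - p)] == x[(p + 1):L] & x[1:(L - p)] != "#")
    score[k] <- max(roll_mean(m, min(2L * p, length(m))))
  }
  if (max(score) < min_copy_identity) return(NULL)
  p <- ps[which.max(score)]
  # harmonic reduction: the smallest divisor scoring within 0.05 of the best
  divs <- ps[p %% ps == 0L & ps < p]
  for (d in sort(divs)) {
    if (score[match(d, ps)] >= max(score) - 0.05) { p <- d; break }
  }
  m <- as.numeric(x[1:(L - p)] == x[(p + 1):L] & x[1:(L - p)] != "#")
  r <- roll_mean(m, min(p, length(m)))
  ok <- r >= min_copy_identity
  peak <- which.max(r)
  # degenerate candidates are masked (accept = FALSE), never returned as
  # NULL: aborting here would hide weaker but genuine arrays at other
  # periods
  if (!ok[peak])
    return(list(accept = FALSE, iv = interval(peak, min(peak + p, L + 1L))))
  a <- peak; b <- peak
  while (a > 1L && ok[a - 1L]) a <- a - 1L
  while (b < length(ok) && ok[b + 1L]) b <- b + 1L
  # phase: the windowed run start can drift into the flank, so copy
  # boundaries are re-derived by choose_phase (most supported copies win)
  R_end <- b + p
  best_o <- choose_phase(x, a, R_end, p, min_copy_identity)
  n_full <- (R_end - best_o + 1L) %/% p
  reject_iv <- interval(a, min(R_end + 1L, L + 1L))
  if (n_full < 2L) return(list(accept = FALSE, iv = reject_iv))
  starts <- best_o + p * (0:(n_full - 1L))
  copies <- vapply(starts, function(st) paste(x[st:(st + p - 1L)], collapse = ""),
                   character(1))
  clean <- !grepl("#", copies, fixed = TRUE)
  if (!any(clean)) return(list(accept = FALSE, iv = reject_iv))
  cons <- build_monomer_consensus(copies[clean])
  idents <- vapply(copies, pid, numeric(1), b = cons, USE.NAMES = FALSE)
  pass <- idents >= min_copy_identity
  if (!any(pass)) return(list(accept = FALSE, iv = reject_iv))
  # array boundaries are determined independently of the copy phase: from
  # the most confident copy, the sequence is compared base-by-base to the
  # periodic continuation of the consensus in both directions, and each
  # boundary is placed at the matches-minus-mismatches maximum. Inside the
  # array the score rises, in unrelated flank it falls, so a true edge --
  # including a mid-copy truncation point -- is found exactly on clean
  # arrays, whichever rotation the consensus happens to be in.
  anchor <- starts[which(pass)[which.max(idents[pass])]]
  consv <- s2c(cons)
  ref <- consv[((seq_len(L) - anchor) %% p) + 1L]
  eq <- (x == ref) & x != "#"
  step <- ifelse(eq, 1, -2)   # asymmetric: flank excursions decay quickly
  right_range <- (anchor + p - 1L):L
  cumR <- cumsum(step[right_range])
  b2 <- right_range[which.max(cumR)] + 1L       # half-open end
  left_range <- anchor:1L                       # walking leftward
  cumL <- cumsum(step[left_range])
  a2 <- left_range[which.max(cumL)]
  iv <- interval(a2, b2)
  copy_number <- round1_half_up(interval_length(iv) / p)
  if (copy_number < min_copies)
    return(list(accept = FALSE, iv = iv))
  # rebuild consensus and identities over full copies phased from the left
  # boundary (so the reported consensus starts where the array starts)
  n_fin <- (b2 - a2) %/% p
  if (n_fin < 1L) return(list(accept = FALSE, iv = iv))
  fst <- a2 + p * (0:(n_fin - 1L))
  fcop <- vapply(fst, function(st) paste(x[st:(st + p - 1L)], collapse = ""),
                 character(1))
  cons <- build_monomer_consensus(fcop)
  mean_id <- mean(vapply(fcop, pid, numeric(1), b = cons, USE.NAMES = FALSE))
  # a consensus that is itself periodic below min_monomer is a harmonic of a
  # shorter repeat (e.g. a subTIR unit array seen at 3x its unit length):
  # rejected, but masked so the search can move on
  if (has_subperiod(cons, as.integer(min_monomer) - 1L, min_copy_identity))
    return(list(accept = FALSE, iv = iv))
  list(accept = TRUE, iv = iv,
       array = list(iv = iv, monomer_len = as.integer(p), consensus = cons,
                    copy_number = copy_number, mean_copy_identity = mean_id))
}

#' @noRd
has_subperiod <- function(cons, max_d, thr) {
  x <- s2c(cons)
  L <- length(x)
  for (d in seq_len(min(max_d, L - 1L))) {
    if (mean(x[1:(L - d)] == x[(d + 1):L]) >= thr) return(TRUE)
  }
  FALSE
}

#' Locate a satellite array relative to an element's coding region
#'
#' @param element Element model with `coding_ivs` in element coordinates and
#'   a `span`.
#' @param array A satellite array (element of [detect_tandem_array()]
#'   output) with `iv` in element coordinates.
#' @return List with `region` (`"five_prime"`, `"internal"`,
#'   `"three_prime"`), `dist_to_3prime` (bp from array end to the element 3'
#'   terminus) and `flagged` (TRUE when the array overlaps coding sequence).
#' @export
locate_array_in_element <- function(element, array) {
  span_len <- interval_length(element$span)
  iv <- as_interval(array$iv)
  if (iv$start < 1L || iv$end > span_len + 1L)
    stop("array interval lies outside the element span")
  coding <- lapply(element$coding_ivs, as_interval)
  overlaps <- length(coding) > 0L &&
    any(vapply(coding, iv_overlaps, logical(1), b = iv))
  cod_min <- if (length(coding)) min(vapply(coding, `[[`, integer(1), "start")) else NA
  cod_max <- if (length(coding)) max(vapply(coding, `[[`, integer(1), "end")) else NA
  region <- if (overlaps) "internal"
  else if (!is.na(cod_min) && iv$end <= cod_min) "five_prime"
  else if (!is.na(cod_max) && iv$start >= cod_max) "three_prime"
  else "internal"
  list(region = region, dist_to_3prime = span_len + 1L - iv$end,
       flagged = overlaps)
}
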