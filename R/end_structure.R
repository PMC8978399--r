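# Terminal-structure detection: self-dot-plots, CACTA-anchored TIR pairs,
# subTIR periodic-unit arrays, element boundaries and completeness.

#' Exact-match self-dot-plot
#'
#' All exact `word`-length matches of a sequence against itself (direct
#' orientation) and, optionally, against its reverse complement (inverted
#' orientation). The main diagonal is included; direct hits are symmetric.
#' Mirrored off-diagonal bands at the element termini are the dot-plot
#' signature of subTIR arrays; parallel diagonals spaced by the monomer
#' length are the signature of a tandem satellite array.
#'
#' @param s DNA string.
#' @param word k-mer length, `1 <= word <= nchar(s)`.
#' @param include_inverted Also report inverted-orientation matches.
#' @return data.frame with columns `a`, `b` (1-based k-mer start positions)
#'   and `orientation` (`"direct"` or `"inverted"`). For inverted hits, `b`
#'   is the start of the k-mer whose reverse complement matches the k-mer
#'   at `a`.
#' @export
self_dotplot <- function(s, word, include_inverted = FALSE) {
  check_dna(s)
  word <- as.integer(word)
  L <- nchar(s)
  if (word < 1L || word > L) stop("word must be between 1 and nchar(s)")
  starts <- 1L:(L - word + 1L)
  kmers <- substring(s, starts, starts + word - 1L)
  pair_up <- function(xs, ys, orientation) {
    groups <- split(seq_along(ys), ys)
    hits_a <- integer(0); hits_b <- integer(0)
    gx <- split(seq_along(xs), xs)
    common <- intersect(names(gx), names(groups))
    for (k in common) {
      ia <- gx[[k]]; ib <- groups[[k]]
      hits_a <- c(hits_a, rep(ia, each = length(ib)))
      hits_b <- c(hits_b, rep(ib, times = length(ia)))
    }
    if (length(hits_a) == 0L)
      return(data.frame(a = integer(), b = integer(),
                        orientation = character()))
    data.frame(a = hits_a, b = hits_b, orientation = orientation)
  }
  out <- pair_up(kmers, kmers, "direct")
  if (include_inverted) {
    rk <- vapply(kmers, revcomp, character(1), USE.NAMES = FALSE)
    out <- rbind(out, pair_up(kmers, rk, "inverted"))
  }
  out[order(out$orientation, out$a, out$b), , drop = FALSE]
}

#' Write a dot-plot hit list to TSV
#' @param dp data.frame from [self_dotplot()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dotplot_tsv <- function(dp, path) {
  utils::write.table(dp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect a CACTA-anchored terminal inverted repeat pair
#'
#' Requires the 5' terminus to begin with `motif` and the 3' terminus to end
#' with its reverse complement (`cacta_intact`). The 5' prefix is then
#' compared position-wise against the reverse complement of the 3' suffix
#' over every length in `[min_len, max_len]`; among lengths whose pair
#' identity reaches `min_pair_identity`, the one maximizing matches minus
#' mismatches is reported (ties to the longer length). The match-minus-
#' mismatch criterion stops the TIR at its true extent: extending a perfect
#' repeat into unrelated flanking sequence can keep identity above the
#' threshold but always lowers the score. Absence of a TIR is a valid
#' result (`NULL`), not an error.
#'
#' @param s Candidate element sequence, at least `2 * max_len` bp.
#' @param motif Terminal anchor motif (default `"CACTA"`).
#' @param min_len,max_len TIR length search range in bp.
#' @param min_pair_identity Minimum position-wise identity between the two
#'   TIR copies (inverted comparison).
#' @return `NULL`, or a list with `left_seq`, `right_seq`, `left_iv`,
#'   `right_iv`, `length`, `pair_identity`, `cacta_intact`.
#' @export
find_tir <- function(s, motif = "CACTA", min_len = 25L, max_len = 40L,
                     min_pair_identity = 0.70) {
  check_dna(s)
  L <- nchar(s)
  if (L < 2L * max_len)
    stop("sequence shorter than 2 * max_len; cannot search for a TIR pair")
  rc_motif <- revcomp(motif)
  if (substr(s, 1L, nchar(motif)) != motif) return(NULL)
  if (substr(s, L - nchar(rc_motif) + 1L, L) != rc_motif) return(NULL)
  lens <- seq(as.integer(min_len), as.integer(max_len))
  pids <- vapply(lens, function(len)
    ungapped_identity(substr(s, 1L, len),
                      revcomp(substr(s, L - len + 1L, L))), numeric(1))
  score <- lens * (2 * pids - 1)  # matches minus mismatches
  pass <- pids >= min_pair_identity
  if (!any(pass)) return(NULL)
  best <- max(score[pass])
  len <- max(lens[pass & score == best])
  pid <- pids[lens == len]
  list(left_seq = substr(s, 1L, len),
       right_seq = substr(s, L - len + 1L, L),
       left_iv = interval(1L, len + 1L),
       right_iv = interval(L - len + 1L, L + 1L),
       length = len, pair_identity = pid, cacta_intact = TRUE)
}

#' Estimate the repeat-unit length of a periodic window
#'
#' For each candidate period `p` the mean position-wise identity between the
#' window and itself shifted by `p` is computed; the maximizing period is
#' returned, ties broken toward the smaller period (so perfect harmonics
#' resolve to the fundamental unit).
#'
#' @param window DNA string, at least `4 * max(unit_range)` bp.
#' @param unit_range Integer pair, the inclusive period search range.
#' @return Integer period in bp. The full identity-vs-shift curve is attached
#'   as attribute `"curve"`.
#' @export
estimate_unit_length <- function(window, unit_range = c(10L, 20L)) {
  check_dna(window)
  L <- nchar(window)
  pmax_ <- max(unit_range)
  if (L < 4L * pmax_)
    stop("window too short: need at least 4 * max(unit_range) bp")
  x <- s2c(window)
  ps <- seq(min(unit_range), pmax_)
  curve <- vapply(ps, function(p) mean(x[1:(L - p)] == x[(p + 1):L]),
                  numeric(1))
  best <- ps[which.max(curve)]  # which.max takes the first (smallest) maximum
  structure(as.integer(best), curve = stats::setNames(curve, ps))
}

#' Greedy non-overlapping scan for copies of a motif
#'
#' Left-to-right: at each position the window of motif length is compared to
#' the motif; on a hit (identity at or above threshold) the copy is recorded
#' and the scan jumps past it, otherwise it advances one base. Leftmost
#' placement wins ties by construction.
#' @noRd
greedy_motif_scan <- function(s, motif, min_identity) {
  p <- nchar(motif)
  L <- nchar(s)
  mv <- s2c(motif)
  x <- s2c(s)
  starts <- integer(0); idents <- numeric(0)
  j <- 1L
  while (j <= L - p + 1L) {
    idv <- mean(x[j:(j + p - 1L)] == mv)
    if (idv >= min_identity) {
      starts <- c(starts, j); idents <- c(idents, idv)
      j <- j + p
    } else j <- j + 1L
  }
  data.frame(start = starts, end = starts + p, identity = idents)
}

#' Keep the largest chain of closely spaced hits
#'
#' subTIR units form a contiguous terminal array, so isolated chance
#' matches elsewhere in the window must not be counted. Hits are chained
#' while the gap to the previous hit is at most one unit length -- which
#' also keeps a chain intact across a single diverged (uncounted) copy --
#' and the largest chain wins, ties going to the chain nearest the
#' terminus.
#' @noRd
cluster_hits <- function(hits, p, gap_max = p) {
  if (nrow(hits) <= 1L) return(hits)
  gaps <- hits$start[-1L] - hits$end[-nrow(hits)]
  grp <- cumsum(c(0L, as.integer(gaps > gap_max)))
  sizes <- tabulate(grp + 1L)
  hits[grp == (which.max(sizes) - 1L), , drop = FALSE]
}

#' Locate the best periodic run at a given period and phase its copies
#'
#' The run is the maximal stretch where the lag-`p` match profile (rolling
#' mean, window `p`) stays at or above `min_identity`. Because that windowed
#' run start can drift into similar flanking sequence, the copy phase is
#' re-derived as the offset maximizing mean adjacent-copy identity (leftmost
#' among ties), which aligns the copy grid with the true array boundary.
#' Returns NULL when no window reaches `min_identity`.
#' @noRd
periodic_run <- function(s, p, min_identity) {
  L <- nchar(s)
  if (L < 2L * p) return(NULL)
  x <- s2c(s)
  m <- as.numeric(x[1:(L - p)] == x[(p + 1):L])
  r <- roll_mean(m, p)                    # r[i]: copy at i matches copy at i+p
  ok <- r >= min_identity
  if (!any(ok)) return(NULL)
  peak <- which.max(r)
  if (!ok[peak]) peak <- which(ok)[1L]
  a <- peak; b <- peak
  while (a > 1L && ok[a - 1L]) a <- a - 1L
  while (b < length(ok) && ok[b + 1L]) b <- b + 1L
  R_end <- b + p                          # last supported position
  best_o <- choose_phase(x, a, R_end, p, min_identity)
  n_full <- (R_end - best_o + 1L) %/% p
  if (n_full < 2L) return(NULL)
  starts <- best_o + p * (0:(n_full - 1L))
  list(start = best_o, copies = substring(s, starts, starts + p - 1L))
}

#' Localized period estimate: best rolling mean of the lag-p match profile
#' (window 3p), so a short array inside a long flank is not diluted.
#' @noRd
est_period_local <- function(s, unit_range, min_identity) {
  L <- nchar(s)
  x <- s2c(s)
  ps <- seq(min(unit_range), max(unit_range))
  ps <- ps[2L * ps < L]
  if (length(ps) == 0L) return(NULL)
  score <- vapply(ps, function(p) {
    m <- as.numeric(x[1:(L - p)] == x[(p + 1):L])
    max(roll_mean(m, min(3L * p, length(m))))
  }, numeric(1))
  if (max(score) < min_identity) return(NULL)
  as.integer(ps[which.max(score)])
}

#' Annotate the subterminal repeat (subTIR) structure of an element
#'
#' The unit length is estimated in the 5' terminal window; each terminal
#' window then derives a phase-canonical unit consensus from its own
#' periodic run (a tandem unit is only defined up to rotation, and a
#' rotation chosen at one end need not tile the other end's array) and is
#' scanned greedily for non-overlapping full copies at or above
#' `min_copy_identity` -- in direct orientation at the 5' end and inverted
#' (reverse-complement) orientation at the 3' end. Counted copies must form
#' a contiguous chain (gaps of at most one unit length, so a single
#' diverged copy does not break the chain); isolated chance matches
#' elsewhere in the window are not counted. The reported motif is the 5'
#' consensus in direct orientation; partial units at array edges are never
#' counted.
#'
#' @param s Element sequence, at least `2 * end_window` bp.
#' @param end_window Terminal window size in bp scanned at each end.
#' @param unit_range Period search range in bp.
#' @param min_copy_identity Minimum identity of a counted copy to the motif.
#' @return A list with `motif`, `unit_length`, `copies` (data.frame of
#'   `start`, `end`, `strand`, `identity`, `end_label` in element
#'   coordinates), `n_5prime`, `n_3prime`, `n_total`. When no periodic
#'   structure is found the annotation has `NA` motif and zero copies.
#' @export
detect_subtir <- function(s, end_window = 600L, unit_range = c(10L, 20L),
                          min_copy_identity = 0.80) {
  check_dna(s)
  L <- nchar(s)
  if (L < 2L * end_window)
    stop("sequence shorter than 2 * end_window")
  w5 <- substr(s, 1L, end_window)
  w3 <- substr(s, L - end_window + 1L, L)
  empty <- list(motif = NA_character_, unit_length = NA_integer_,
                copies = data.frame(start = integer(), end = integer(),
                                    strand = character(), identity = numeric(),
                                    end_label = character()),
                n_5prime = 0L, n_3prime = 0L, n_total = 0L)
  # discovery is run at a relaxed threshold so that the motif consensus can
  # be built from as many copies as possible; the reported counts are then
  # produced at the full copy-identity contract
  disc_thr <- max(min_copy_identity - 0.10, 0.5)
  # localized period estimate: a short unit array must not be diluted by the
  # rest of the window (see est_period_local)
  p <- est_period_local(w5, unit_range, disc_thr)
  if (is.null(p)) return(empty)
  run <- periodic_run(w5, p, disc_thr)
  if (is.null(run)) return(empty)
  # per-end motif derivation: the unit of a tandem array is only defined up
  # to rotation, and a rotation chosen at one end need not tile the other
  # end's array (its junction-straddling copy would depend on flanking
  # bases). Each terminal window therefore derives and counts its own
  # phase-canonical consensus; the 5' consensus is the reported motif, in
  # direct orientation. The 3' window is processed on its reverse
  # complement, which presents the same direct-array layout as the 5' end.
  end_motif <- function(w) {
    rn <- periodic_run(w, p, disc_thr)
    if (is.null(rn)) return(NULL)
    m0 <- build_monomer_consensus(rn$copies)
    ha <- greedy_motif_scan(w, m0, disc_thr)
    if (nrow(ha) >= 2L)
      build_monomer_consensus(substring(w, ha$start, ha$end - 1L))
    else m0
  }
  motif <- end_motif(w5)
  if (is.null(motif)) motif <- build_monomer_consensus(run$copies)
  hits5 <- cluster_hits(greedy_motif_scan(w5, motif, min_copy_identity), p)
  w3rc <- revcomp(w3)
  motif3 <- end_motif(w3rc)
  if (is.null(motif3)) motif3 <- motif
  hits3rc <- cluster_hits(greedy_motif_scan(w3rc, motif3, min_copy_identity), p)
  # map reverse-complement coordinates back onto the 3' window
  hits3 <- if (nrow(hits3rc)) data.frame(
    start = end_window - hits3rc$end + 2L,
    end = end_window - hits3rc$start + 2L,
    identity = hits3rc$identity) else hits3rc
  off3 <- L - end_window
  copies <- rbind(
    if (nrow(hits5)) data.frame(start = hits5$start, end = hits5$end,
                                strand = "+", identity = hits5$identity,
                                end_label = "five_prime"),
    if (nrow(hits3)) data.frame(start = hits3$start + off3,
                                end = hits3$end + off3,
                                strand = "-", identity = hits3$identity,
                                end_label = "three_prime"))
  if (is.null(copies)) copies <- empty$copies
  list(motif = motif, unit_length = p, copies = copies,
       n_5prime = nrow(hits5), n_3prime = nrow(hits3),
       n_total = nrow(hits5) + nrow(hits3))
}

#' Check for a target-site duplication flanking an element
#'
#' CACTA insertion creates a short (canonically 3-bp) duplication of the host
#' target site. The `tsd_len`-mer immediately 5' of the element span is
#' returned iff it equals the `tsd_len`-mer immediately 3' of the span.
#'
#' @param contig Contig sequence (character string).
#' @param span Element [interval()] within the contig.
#' @param tsd_len Duplication length in bp.
#' @return The TSD string, or `NULL` when the flanks differ.
#' @export
check_tsd <- function(contig, span, tsd_len = 3L) {
  check_dna(contig)
  span <- as_interval(span)
  tsd_len <- as.integer(tsd_len)
  if (span$start - tsd_len < 1L || span$end + tsd_len - 1L > nchar(contig))
    stop("insufficient flanking sequence for a ", tsd_len, "-bp TSD check")
  left <- substr(contig, span$start - tsd_len, span$start - 1L)
  right <- substr(contig, span$end, span$end + tsd_len - 1L)
  if (left == right) left else NULL
}

#' Call a CACTA element around a positioned transposase domain
#'
#' Mirrors the annotation order of TE pipelines built on protein-domain
#' positioning: the transposase anchor comes first, terminal structure is
#' searched in the surrounding sequence. Within `max_flank` of the anchor,
#' candidate 5' starts (occurrences of the CACTA motif) and 3' ends
#' (occurrences of its reverse complement) are paired and tested with
#' [find_tir()]; a candidate with an intact TIR pair and consistent subTIR
#' arrays on both ends is called `complete`. Failing that, a subTIR unit
#' array is sought directly on both flanks (direct copies 5', inverted
#' copies 3') and bounds a `subtir_only` call. Otherwise the call is
#' `incomplete` with the searched window as span.
#'
#' @param contig Contig sequence.
#' @param tpase_iv [interval()] of the transposase (Transposase_21) hit in
#'   contig coordinates.
#' @param max_flank Search distance on each side of the anchor, bp.
#' @param config Optional list overriding detection thresholds:
#'   `tir_motif`, `tir_min_len`, `tir_max_len`, `min_pair_identity`,
#'   `end_window`, `unit_range`, `min_copy_identity`, `min_copies_per_end`,
#'   `tsd_len`.
#' @param contig_id Identifier recorded in the element model.
#' @return An element model: list with `contig_id`, `span`, `completeness`
#'   (`"complete"`, `"subtir_only"` or `"incomplete"`), `tir`, `subtir`,
#'   `tsd`, `tpase_iv`, and empty slots `coding_ivs`, `domains`, `cda`,
#'   `captures`, `arrays` filled by downstream stages.
#' @export
call_element <- function(contig, tpase_iv, max_flank = 15000L,
                         config = list(), contig_id = "contig") {
  check_dna(contig)
  tpase_iv <- as_interval(tpase_iv)
  L <- nchar(contig)
  if (tpase_iv$start < 1L || tpase_iv$end > L + 1L)
    stop("tpase_iv lies outside the contig")
  cfg <- utils::modifyList(list(
    tir_motif = "CACTA", tir_min_len = 25L, tir_max_len = 40L,
    min_pair_identity = 0.70, end_window = 600L, unit_range = c(10L, 20L),
    min_copy_identity = 0.80, min_copies_per_end = 3L, tsd_len = 3L), config)

  win_start <- max(1L, tpase_iv$start - as.integer(max_flank))
  win_end <- min(L + 1L, tpase_iv$end + as.integer(max_flank))
  w <- substr(contig, win_start, win_end - 1L)
  t_start <- tpase_iv$start - win_start + 1L  # anchor in window coords
  t_end <- tpase_iv$end - win_start + 1L

  model <- list(contig_id = contig_id,
                span = interval(win_start, win_end),
                completeness = "incomplete",
                tir = NULL, subtir = NULL, tsd = NULL,
                tpase_iv = tpase_iv,
                coding_ivs = list(), domains = NULL, cda = NULL,
                captures = NULL, arrays = list())
  class(model) <- "cacta_element"

  finish <- function(model) {
    model$tsd <- tryCatch(check_tsd(contig, model$span, cfg$tsd_len),
                          error = function(e) NULL)
    model
  }

  # --- complete: CACTA-intact TIR pair + subTIR arrays on both ends
  lefts <- gregexpr(cfg$tir_motif, substr(w, 1L, t_start), fixed = TRUE)[[1]]
  lefts <- lefts[lefts > 0L]
  rc <- revcomp(cfg$tir_motif)
  rights <- gregexpr(rc, w, fixed = TRUE)[[1]]
  rights <- rights[rights > 0L]
  rights <- rights[rights + nchar(rc) - 1L >= t_end]  # element must contain anchor
  cands <- list()
  for (l in lefts) for (r in rights) {
    r_end <- r + nchar(rc)  # half-open end in window coords
    if (r_end - l < 2L * cfg$tir_max_len) next
    tir <- find_tir(substr(w, l, r_end - 1L), cfg$tir_motif,
                    cfg$tir_min_len, cfg$tir_max_len, cfg$min_pair_identity)
    if (!is.null(tir))
      cands[[length(cands) + 1L]] <- list(l = l, r_end = r_end, tir = tir)
  }
  if (length(cands)) {
    score <- vapply(cands, function(cd)
      cd$tir$pair_identity * 1e6 + cd$tir$length * 1e3 +
        (cd$r_end - cd$l) * 1e-6, numeric(1))
    for (cd in cands[order(score, decreasing = TRUE)]) {
      elem <- substr(w, cd$l, cd$r_end - 1L)
      if (nchar(elem) < 2L * cfg$end_window) next
      st <- detect_subtir(elem, cfg$end_window, cfg$unit_range,
                          cfg$min_copy_identity)
      if (st$n_5prime >= cfg$min_copies_per_end &&
          st$n_3prime >= cfg$min_copies_per_end) {
        off <- win_start + cd$l - 2L
        st$copies$start <- st$copies$start + off
        st$copies$end <- st$copies$end + off
        tir <- cd$tir
        tir$left_iv <- iv_shift(tir$left_iv, off)
        tir$right_iv <- iv_shift(tir$right_iv, off)
        model$span <- interval(win_start + cd$l - 1L, win_start + cd$r_end - 1L)
        model$completeness <- "complete"
        model$tir <- tir
        model$subtir <- st
        return(finish(model))
      }
    }
  }

  # --- subtir_only: terminal unit arrays without an intact TIR pair
  left_flank <- substr(w, 1L, t_start)
  right_flank <- substr(w, t_end, nchar(w))
  p <- if (nchar(left_flank) >= 4L * max(cfg$unit_range))
    est_period_local(left_flank, cfg$unit_range, cfg$min_copy_identity)
  if (!is.null(p)) {
    run <- periodic_run(left_flank, p, cfg$min_copy_identity)
    if (!is.null(run)) {
      motif <- build_monomer_consensus(run$copies)
      h5 <- cluster_hits(greedy_motif_scan(left_flank, motif,
                                           cfg$min_copy_identity), p)
      h3 <- cluster_hits(greedy_motif_scan(right_flank, revcomp(motif),
                                           cfg$min_copy_identity), p)
      if (nrow(h5) >= cfg$min_copies_per_end &&
          nrow(h3) >= cfg$min_copies_per_end) {
        el_start <- win_start + h5$start[1L] - 1L
        el_end <- win_start + (t_end - 1L) + h3$end[nrow(h3)] - 1L
        model$span <- interval(el_start, el_end)
        model$completeness <- "subtir_only"
        off5 <- win_start - 1L
        off3 <- win_start + t_end - 2L
        copies <- rbind(
          data.frame(start = h5$start + off5, end = h5$end + off5,
                     strand = "+", identity = h5$identity,
                     end_label = "five_prime"),
          data.frame(start = h3$start + off3, end = h3$end + off3,
                     strand = "-", identity = h3$identity,
                     end_label = "three_prime"))
        model$subtir <- list(motif = motif, unit_length = nchar(motif),
                             copies = copies,
                             n_5prime = nrow(h5), n_3prime = nrow(h3),
                             n_total = nrow(h5) + nrow(h3))
        return(finish(model))
      }
    }
  }

  model  # incomplete; span is the searched window
}
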