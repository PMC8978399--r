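# Synthetic CACTA elements with exact ground truth. The generator realizes
# the structural grammar of the element family: 3-bp target-site duplication,
# CACTA-anchored TIR, phased subTIR unit array (direct at the 5' end,
# inverted at the 3' end), a domain-bearing internal region, optional
# captured fragments upstream of TAD, an optional 3'-proximal tandem
# satellite array, and the mirrored 3' terminal structure -- embedded in
# random background under a per-base substitution noise model.

DOMAIN_PLACEHOLDER_LENS <- c(TAD = 240L, Transposase_21 = 630L,
                             DUF4218 = 540L, DUF4216 = 510L,
                             Transposase_24 = 390L, Peptidase_C48 = 120L)

NONSTOP_CODONS <- setdiff(names(CODON_TABLE), STOP_CODONS)

#' @noRd
codon_filler <- function(len, seed) {
  stopifnot(len %% 3L == 0L)
  with_seed(seed, c2s(sample(NONSTOP_CODONS, len %/% 3L, replace = TRUE)))
}

#' Fixed sentinel sequence standing in for a named protein domain
#'
#' Each domain name maps to one fixed, reproducible open-reading-frame
#' segment (no in-frame stops), so that domain "hits" on generator output
#' can be produced by exact matching and carry exact ground-truth
#' coordinates.
#'
#' @param name One of `TAD`, `Transposase_21`, `DUF4218`, `DUF4216`,
#'   `Transposase_24`, `Peptidase_C48`.
#' @return DNA string of the placeholder length for that domain
#'   (Transposase_21: 630 bp, the full-length tnp2 size).
#' @export
domain_placeholder <- function(name) {
  if (!name %in% names(DOMAIN_PLACEHOLDER_LENS))
    stop("unknown domain placeholder: ", name)
  codon_filler(DOMAIN_PLACEHOLDER_LENS[[name]], sum(utf8ToInt(name)))
}

#' Specify a synthetic CACTA element
#'
#' @param tir TIR sequence; must begin with `CACTA`.
#' @param subtir_motif subTIR unit motif, 10-20 bp, given in 5' direct
#'   orientation.
#' @param n5,n3 Number of unit copies at the 5' (direct) and 3' (inverted)
#'   ends.
#' @param orf2_domains Domains of the second ORF, a subset of
#'   `c("Transposase_24", "Peptidase_C48")`; empty for a type-1 element.
#' @param captures Optional data.frame with columns `label`, `seq`,
#'   `offset` -- each fragment is written into the 5' region so that
#'   `offset` bp separate its end from the TAD start. Requires `tad_start`.
#' @param sat_array Optional list `(monomer =, copies =)`; a tandem array
#'   with the given fractional copy number is placed between the coding
#'   region and the 3' terminal structure.
#' @param tsd Optional 3-bp target-site duplication, applied on embedding.
#' @param target_length Optional total element length in bp; the 3' spacer
#'   absorbs the slack. An infeasible target is an error.
#' @param tad_start Optional element coordinate at which the TAD domain must
#'   begin (fixes the 5' spacer).
#' @param gap5 5' spacer length when `tad_start` is not given.
#' @param ablate_tir When TRUE the terminal CACTA anchors are overwritten
#'   (the TIR pair is destroyed) while the subTIR arrays stay intact,
#'   emulating elements with almost complete ends.
#' @param mut_rate Per-base substitution probability in `[0, 0.25]` applied
#'   to the finished element.
#' @param seed Integer seed; all randomness in the element derives from it.
#' @return An element spec (list) for [build_element()].
#' @export
element_spec <- function(tir, subtir_motif, n5, n3,
                         orf2_domains = character(),
                         captures = NULL, sat_array = NULL, tsd = NULL,
                         target_length = NULL, tad_start = NULL,
                         gap5 = 600L, ablate_tir = FALSE,
                         mut_rate = 0, seed = 1L) {
  check_dna(tir, "tir"); check_dna(subtir_motif, "subtir_motif")
  if (substr(tir, 1L, 5L) != "CACTA") stop("tir must begin with CACTA")
  if (nchar(subtir_motif) < 10L || nchar(subtir_motif) > 20L)
    stop("subtir_motif must be 10-20 bp")
  if (n5 < 0L || n3 < 0L) stop("copy counts must be non-negative")
  if (mut_rate < 0 || mut_rate > 0.25) stop("mut_rate must be in [0, 0.25]")
  if (!all(orf2_domains %in% c("Transposase_24", "Peptidase_C48")))
    stop("orf2_domains must be a subset of Transposase_24, Peptidase_C48")
  if (!is.null(captures) && is.null(tad_start))
    stop("captures require tad_start")
  if (!is.null(tsd)) {
    check_dna(tsd, "tsd")
    if (nchar(tsd) != 3L) stop("tsd must be 3 bp")
  }
  list(tir = tir, subtir_motif = subtir_motif,
       n5 = as.integer(n5), n3 = as.integer(n3),
       orf2_domains = orf2_domains, captures = captures,
       sat_array = sat_array, tsd = tsd,
       target_length = if (!is.null(target_length)) as.integer(target_length),
       tad_start = if (!is.null(tad_start)) as.integer(tad_start),
       gap5 = as.integer(gap5), ablate_tir = isTRUE(ablate_tir),
       mut_rate = mut_rate, seed = as.integer(seed))
}

#' Element spec reconstructing a described Jozin family
#'
#' Presets encode each family's published TIR, subTIR motif, per-end unit
#' counts, CDA type and total element length (see [jozin_families]); the
#' C. vulvaria preset additionally carries its two Neprosin-superfamily
#' captured fragments (113 and 203 bp, the latter ending 754 bp upstream of
#' TAD), and `"quinoa_scaffold3389"` is the satellite-bearing element: 16523
#' bp with a 32.5-copy array of the 171-bp monomer and subTIR-only ends.
#'
#' @param family One of `jozin_families$family` or `"quinoa_scaffold3389"`.
#' @param mut_rate,seed Passed to [element_spec()].
#' @return An element spec.
#' @export
jozin_element_spec <- function(family, mut_rate = 0, seed = 1L) {
  if (family == "quinoa_scaffold3389") {
    return(element_spec(
      tir = jozin_tirs[["quinoa_scaffold3500"]],
      subtir_motif = "TATTTGTAACTA", n5 = 8L, n3 = 8L,
      orf2_domains = "Transposase_24",
      sat_array = list(monomer = chenopodium_sat_monomer, copies = 32.5),
      target_length = 16523L, tad_start = 1679L, ablate_tir = TRUE,
      tsd = "TAC", mut_rate = mut_rate, seed = seed))
  }
  row <- jozin_families[jozin_families$family == family, ]
  if (nrow(row) != 1L) stop("unknown family: ", family)
  orf2 <- switch(row$cda, type1 = character(),
                 type2 = "Peptidase_C48",
                 type3 = "Transposase_24",
                 type4 = c("Transposase_24", "Peptidase_C48"))
  captures <- NULL; tad_start <- NULL
  if (family == "vulvaria") {
    captures <- data.frame(
      label = c("Neprosin_pfam14365", "Neprosin_pfam03080"),
      seq = c(codon_filler(113L + 1L, 401L), codon_filler(204L, 402L)),
      offset = c(1204L, 754L), stringsAsFactors = FALSE)
    captures$seq <- substr(captures$seq, 1L, c(113L, 203L))
    tad_start <- 4211L
  }
  element_spec(tir = row$tir, subtir_motif = row$motif,
               n5 = row$n5, n3 = row$n3, orf2_domains = orf2,
               captures = captures, tsd = "TAC",
               target_length = row$length, tad_start = tad_start,
               mut_rate = mut_rate, seed = seed)
}

#' Build a synthetic element from a spec
#'
#' Assembles `TIR + direct subTIR array + 5' spacer (with any captured
#' fragments written in) + ORF1 (TAD, Transposase_21, DUF4218, DUF4216) +
#' optional ORF2 + optional satellite array + 3' spacer + inverted subTIR
#' array + reverse-complement TIR`, applies the substitution noise model,
#' and returns the sequence together with exact pre-mutation ground truth.
#'
#' @param spec From [element_spec()].
#' @return List with `seq` (DNA string) and `truth`: `length`, `tir_ivs`,
#'   `subtir_copies` (data.frame), `motif`, `n5`, `n3`, `orf_ivs`,
#'   `domain_ivs` (data.frame with `name`, `start`, `end`, `orf`),
#'   `captures`, `array_iv`, `sat_monomer_len`, `sat_copy_number`, `tsd`,
#'   `cda`, `spec`.
#' @export
build_element <- function(spec) {
  p <- nchar(spec$subtir_motif)
  tir_len <- nchar(spec$tir)
  sub5 <- strrep(spec$subtir_motif, spec$n5)
  sub3 <- revcomp(strrep(spec$subtir_motif, spec$n3))

  # ORF1: ATG + TAD + link + Transposase_21 + link + DUF4218 + link + DUF4216
  # + link + stop  (3294 bp total)
  link_len <- 342L
  orf1_doms <- c("TAD", "Transposase_21", "DUF4218", "DUF4216")
  orf1_parts <- character(0); dom_off1 <- integer(0)
  cursor <- 3L  # after ATG
  for (i in seq_along(orf1_doms)) {
    orf1_parts <- c(orf1_parts, domain_placeholder(orf1_doms[i]),
                    codon_filler(link_len, spec$seed * 10L + i))
    dom_off1 <- c(dom_off1, cursor)
    cursor <- cursor + DOMAIN_PLACEHOLDER_LENS[[orf1_doms[i]]] + link_len
  }
  orf1 <- paste0("ATG", paste(orf1_parts, collapse = ""), "TAA")
  # ORF2 (optional): ATG + Transposase_24 + link + Peptidase_C48 + stop
  orf2 <- ""; dom_off2 <- integer(0); orf2_doms <- spec$orf2_domains
  if ("Peptidase_C48" %in% orf2_doms &&
      match("Peptidase_C48", orf2_doms) < length(orf2_doms))
    orf2_doms <- c(setdiff(orf2_doms, "Peptidase_C48"), "Peptidase_C48")
  if (length(orf2_doms)) {
    cursor <- 3L; parts <- character(0)
    for (i in seq_along(orf2_doms)) {
      parts <- c(parts, domain_placeholder(orf2_doms[i]),
                 if (i < length(orf2_doms)) codon_filler(60L, spec$seed * 10L + 7L))
      dom_off2 <- c(dom_off2, cursor)
      cursor <- cursor + DOMAIN_PLACEHOLDER_LENS[[orf2_doms[i]]] +
        if (i < length(orf2_doms)) 60L else 0L
    }
    orf2 <- paste0("ATG", paste(parts, collapse = ""), "TAA")
  }

  # 5' spacer
  head_len <- tir_len + nchar(sub5)
  if (!is.null(spec$tad_start)) {
    orf1_start <- spec$tad_start - 3L  # ATG immediately precedes TAD
    gap5 <- orf1_start - head_len - 1L
    if (gap5 < 0L) stop("tad_start too close to the 5' terminal structure")
  } else {
    gap5 <- spec$gap5
    orf1_start <- head_len + gap5 + 1L
  }
  filler5 <- rand_dna(gap5, 0.4, spec$seed * 7L + 1L)
  # captured fragments overwrite the 5' spacer
  cap_truth <- NULL
  if (!is.null(spec$captures)) {
    f5 <- s2c(filler5)
    tad_start <- spec$tad_start
    cap_truth <- data.frame(label = spec$captures$label,
                            start = integer(nrow(spec$captures)),
                            end = integer(nrow(spec$captures)))
    for (i in seq_len(nrow(spec$captures))) {
      fseq <- spec$captures$seq[i]
      st <- tad_start - spec$captures$offset[i] - nchar(fseq)  # element coord
      en <- st + nchar(fseq)
      if (st <= head_len || en > orf1_start)
        stop("capture '", spec$captures$label[i],
             "' does not fit in the 5' spacer")
      rel <- st - head_len  # position within filler5
      f5[rel:(rel + nchar(fseq) - 1L)] <- s2c(fseq)
      cap_truth$start[i] <- st; cap_truth$end[i] <- en
    }
    filler5 <- c2s(f5)
  }

  gap12 <- 200L
  filler12 <- if (nchar(orf2)) rand_dna(gap12, 0.4, spec$seed * 7L + 2L) else ""

  # satellite array
  sat <- ""; sat_len <- 0L
  if (!is.null(spec$sat_array)) {
    mono <- spec$sat_array$monomer
    ml <- nchar(mono)
    total <- as.integer(round(spec$sat_array$copies * ml))
    sat <- substr(strrep(mono, ceiling(total / ml)), 1L, total)
    sat_len <- total
  }
  # the two bases flanking the array on each side must not continue the
  # monomer periodicity, so the array's annotated extent is well-defined
  break_base <- function(avoid) setdiff(c("A", "C", "G", "T"), avoid)[1L]
  # post-array gap is short and fixed so any satellite array sits close to
  # the 3' terminal structure, as observed for real captures
  gap3a <- if (sat_len) 300L else 0L
  filler3a <- rand_dna(gap3a, 0.4, spec$seed * 7L + 3L)
  if (sat_len) {
    for (k in 1:2) {
      pos <- (sat_len + k - 1L) %% ml + 1L
      cont <- substr(mono, pos, pos)
      if (substr(filler3a, k, k) == cont)
        substr(filler3a, k, k) <- break_base(cont)
    }
  }

  fixed_len <- head_len + gap5 + nchar(orf1) +
    (if (nchar(orf2)) gap12 + nchar(orf2) else 0L) +
    gap3a + sat_len + nchar(sub3) + tir_len
  if (!is.null(spec$target_length)) {
    gap3b <- spec$target_length - fixed_len
    if (gap3b < 0L)
      stop("target_length infeasible: fixed parts occupy ", fixed_len, " bp")
  } else gap3b <- 400L
  filler3b <- rand_dna(gap3b, 0.4, spec$seed * 7L + 4L)
  if (sat_len && gap3b > 1L) {
    for (k in 1:2) {
      pos <- ml - k + 1L
      cont <- substr(mono, pos, pos)
      if (substr(filler3b, gap3b - k + 1L, gap3b - k + 1L) == cont)
        substr(filler3b, gap3b - k + 1L, gap3b - k + 1L) <- break_base(cont)
    }
  }

  seq <- paste0(spec$tir, sub5, filler5, orf1,
                if (nchar(orf2)) paste0(filler12, orf2) else "",
                filler3b, sat, filler3a, sub3, revcomp(spec$tir))
  L <- nchar(seq)
  if (isTRUE(spec$ablate_tir)) {
    # destroy the CACTA anchors at both termini; subTIR arrays untouched
    substr(seq, 1L, 5L) <- "GGGGG"
    substr(seq, L - 4L, L) <- "CCCCC"
  }

  # ---- ground truth (pre-mutation, element coordinates)
  pos <- 1L
  tir_left <- interval(1L, tir_len + 1L)
  sub5_ivs <- if (spec$n5) data.frame(
    start = tir_len + 1L + p * (0:(spec$n5 - 1L)),
    end = tir_len + 1L + p * (1:spec$n5), strand = "+",
    end_label = "five_prime") else NULL
  orf1_iv <- interval(orf1_start, orf1_start + nchar(orf1))
  dom1 <- data.frame(name = orf1_doms,
                     start = orf1_start + dom_off1,
                     end = orf1_start + dom_off1 +
                       unname(DOMAIN_PLACEHOLDER_LENS[orf1_doms]),
                     orf = "ORF1")
  orf_ivs <- list(orf1_iv)
  dom_all <- dom1
  cursor <- orf1_start + nchar(orf1)
  if (nchar(orf2)) {
    orf2_start <- cursor + gap12
    orf_ivs <- c(orf_ivs, list(interval(orf2_start, orf2_start + nchar(orf2))))
    dom_all <- rbind(dom_all, data.frame(
      name = orf2_doms, start = orf2_start + dom_off2,
      end = orf2_start + dom_off2 + unname(DOMAIN_PLACEHOLDER_LENS[orf2_doms]),
      orf = "ORF2"))
    cursor <- orf2_start + nchar(orf2)
  }
  array_iv <- NULL
  if (sat_len) {
    array_start <- cursor + gap3b
    array_iv <- interval(array_start, array_start + sat_len)
    cursor <- array_start + sat_len
  }
  sub3_start <- L - tir_len - nchar(sub3) + 1L
  sub3_ivs <- if (spec$n3) data.frame(
    start = sub3_start + p * (0:(spec$n3 - 1L)),
    end = sub3_start + p * (1:spec$n3), strand = "-",
    end_label = "three_prime") else NULL
  tir_right <- interval(L - tir_len + 1L, L + 1L)

  cda <- classify_cda(dom_all$name)$label

  out_seq <- if (spec$mut_rate > 0)
    mutate(seq, spec$mut_rate, spec$seed + 1000L) else seq
  list(seq = out_seq,
       truth = list(
         length = L,
         tir_ivs = list(left = tir_left, right = tir_right),
         subtir_copies = rbind(sub5_ivs, sub3_ivs),
         motif = spec$subtir_motif, n5 = spec$n5, n3 = spec$n3,
         orf_ivs = orf_ivs, domain_ivs = dom_all,
         captures = cap_truth, array_iv = array_iv,
         sat_monomer_len = if (sat_len) nchar(spec$sat_array$monomer),
         sat_copy_number = if (sat_len)
           round1_half_up(sat_len / nchar(spec$sat_array$monomer)),
         tsd = spec$tsd, cda = cda, spec = spec))
}

#' Random background DNA of a given GC content
#' @noRd
rand_dna <- function(len, gc = 0.4, seed = 1L) {
  if (len <= 0L) return("")
  with_seed(seed, c2s(sample(c("A", "T", "G", "C"), len, replace = TRUE,
                             prob = c((1 - gc) / 2, (1 - gc) / 2,
                                      gc / 2, gc / 2))))
}

#' Apply i.i.d. substitutions to a sequence
#'
#' Each position is substituted with probability `rate`; a substituted base
#' becomes one of the three other bases, uniformly. Length is preserved and
#' the result is reproducible for a fixed seed.
#'
#' @param s DNA string.
#' @param rate Substitution probability per base, in `[0, 0.25]`.
#' @param seed Integer seed.
#' @return Mutated DNA string.
#' @export
mutate <- function(s, rate, seed) {
  check_dna(s)
  if (rate < 0 || rate > 0.25) stop("rate must be in [0, 0.25]")
  if (rate == 0) return(s)
  with_seed(seed, {
    x <- s2c(s)
    hit <- which(stats::runif(length(x)) < rate & x != "N")
    if (length(hit)) {
      x[hit] <- vapply(x[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    c2s(x)
  })
}

#' Embed elements in random background, with target-site duplications
#'
#' Elements are inserted at non-overlapping uniform-random points of an
#' i.i.d. background of the requested GC content; when an element's spec
#' carries a TSD, the duplication is written on both flanks. Ground-truth
#' coordinates are lifted to contig space.
#'
#' @param elements List of [build_element()] outputs.
#' @param bg_len Background length in bp; total element length must not
#'   exceed `bg_len / 2`.
#' @param gc Background GC fraction, in `(0, 1)`.
#' @param seed Integer seed.
#' @param contig_id Name of the emitted contig.
#' @return List with `id`, `seq`, `length`, and `truth`: a list (one entry
#'   per element) of lifted ground truths, each with an added `span`
#'   ([interval()] in contig coordinates).
#' @export
embed_in_background <- function(elements, bg_len, gc = 0.4, seed = 1L,
                                contig_id = "synth_contig") {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  total <- sum(vapply(elements, function(e) nchar(e$seq), integer(1)))
  if (total > bg_len / 2)
    stop("total element length exceeds half the background length")
  bg <- rand_dna(bg_len, gc, seed)
  n <- length(elements)
  # insertion points, kept distinct and in order
  pts <- with_seed(seed + 1L, {
    ok <- FALSE
    for (try in 1:100) {
      cand <- sort(sample(seq(10L, bg_len - 10L), n))
      if (n <= 1L || min(diff(cand)) >= 1L) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place elements without overlap")
    cand
  })
  pieces <- character(0)
  truths <- vector("list", n)
  prev <- 1L; offset <- 0L
  for (i in seq_len(n)) {
    el <- elements[[i]]
    tsd <- el$truth$tsd
    tlen <- if (is.null(tsd)) 0L else nchar(tsd)
    pieces <- c(pieces, substr(bg, prev, pts[i] - 1L),
                if (tlen) tsd, el$seq, if (tlen) tsd)
    el_start <- pts[i] + offset + tlen  # contig coord of element base 1
    tr <- lift_truth(el$truth, el_start - 1L)
    tr$span <- interval(el_start, el_start + el$truth$length)
    truths[[i]] <- tr
    offset <- offset + el$truth$length + 2L * tlen
    prev <- pts[i]
  }
  pieces <- c(pieces, substr(bg, prev, bg_len))
  seq <- paste(pieces, collapse = "")
  list(id = contig_id, seq = seq, length = nchar(seq), truth = truths)
}

#' @noRd
lift_truth <- function(truth, by) {
  sh <- function(iv) if (!is.null(iv)) iv_shift(iv, by)
  shdf <- function(df) {
    if (is.null(df)) return(NULL)
    df$start <- df$start + by; df$end <- df$end + by; df
  }
  truth$tir_ivs <- lapply(truth$tir_ivs, sh)
  truth$subtir_copies <- shdf(truth$subtir_copies)
  truth$orf_ivs <- lapply(truth$orf_ivs, sh)
  truth$domain_ivs <- shdf(truth$domain_ivs)
  truth$captures <- shdf(truth$captures)
  truth$array_iv <- sh(truth$array_iv)
  truth
}

#' Write a generator truth table of domain hits (DANTE-style TSV)
#'
#' Emits the contig-coordinate domain intervals of embedded elements in the
#' TSV dialect read by [load_domain_hits()] (coordinates written 1-based
#' inclusive).
#'
#' @param embedded Output of [embed_in_background()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_hits <- function(embedded, path) {
  rows <- do.call(rbind, lapply(embedded$truth, function(tr) {
    df <- tr$domain_ivs
    data.frame(seqid = embedded$id, name = df$name, start = df$start,
               end = df$end - 1L, strand = "+",
               identity = 0.9, similarity = 0.95, aln_len_prop = 1.0,
               interruptions = 0L, length_prop = 1.0)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write generator ground truth as GFF3
#'
#' @param embedded Output of [embed_in_background()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_truth_gff3 <- function(embedded, path) {
  feats <- list()
  add <- function(type, iv, attrs) {
    feats[[length(feats) + 1L]] <<- data.frame(
      seqid = embedded$id, source = "cactascan_sim", type = type,
      start = iv$start, end = iv$end, score = ".", strand = iv$strand,
      phase = ".", attributes = attrs)
  }
  for (i in seq_along(embedded$truth)) {
    tr <- embedded$truth[[i]]
    eid <- sprintf("element%02d", i)
    add("transposable_element", tr$span, paste0("ID=", eid, ";cda=", tr$cda))
    for (side in names(tr$tir_ivs))
      add("terminal_inverted_repeat", tr$tir_ivs[[side]],
          paste0("Parent=", eid, ";side=", side))
    if (!is.null(tr$subtir_copies)) for (j in seq_len(nrow(tr$subtir_copies)))
      add("repeat_region",
          interval(tr$subtir_copies$start[j], tr$subtir_copies$end[j],
                   tr$subtir_copies$strand[j]),
          paste0("Parent=", eid, ";class=subTIR_unit"))
    if (!is.null(tr$array_iv))
      add("satellite_DNA", tr$array_iv, paste0("Parent=", eid))
  }
  write_gff3(do.call(rbind, feats), path)
}
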