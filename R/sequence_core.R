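#' Read a FASTA file
#'
#' Sequences are uppercased on ingest and RNA `U` is converted to `T`.
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA: ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(chartr("Uu", "Tt", as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("malformed FASTA: empty record id")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ", paste(ids[bad], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Watson-Crick reverse complement
#'
#' `N` maps to `N`; any character outside `{A,C,G,T,N}` is an error.
#'
#' @param s DNA string.
#' @return The reverse complement, same length.
#' @examples
#' revcomp("CACTA")  # "TAGTG"
#' @export
revcomp <- function(s) {
  check_dna(s)
  c2s(rev(s2c(chartr("ACGTN", "TGCAN", s))))
}

#' Position-wise (ungapped) identity of two equal-length sequences
#'
#' `N` counts as a mismatch against anything, including `N`: the metric is
#' deterministic and conservative in the presence of ambiguity.
#'
#' @param a,b DNA strings. Must be equal length unless `span` is given.
#' @param span Optional prefix length; only the first `span` positions are
#'   compared.
#' @return Fraction of matching positions, in `[0, 1]`.
#' @export
ungapped_identity <- function(a, b, span = NULL) {
  check_dna(a, "a"); check_dna(b, "b")
  if (is.null(span)) {
    if (nchar(a) != nchar(b))
      stop("sequences have unequal length; give `span` to compare prefixes")
    span <- nchar(a)
  } else {
    span <- as.integer(span)
    if (span < 1L || span > min(nchar(a), nchar(b)))
      stop("`span` must be between 1 and the shorter sequence length")
  }
  av <- s2c(substr(a, 1L, span))
  bv <- s2c(substr(b, 1L, span))
  mean(av == bv & av != "N")
}

#' Identity under a global (Needleman-Wunsch) alignment
#'
#' Aligns the full lengths of both sequences with linear gap penalties and
#' returns matched columns divided by total alignment columns (gap columns
#' included in the denominator). When several alignments are optimal, the
#' "high-road" traceback is used (diagonal preferred over up, up over left),
#' which fixes the reported identity deterministically.
#'
#' @param a,b Non-empty DNA strings.
#' @param match,mismatch,gap Scores (gap is per gapped column).
#' @return Fraction in `[0, 1]`. The optimal score is attached as attribute
#'   `"score"` and the alignment length as `"columns"`.
#' @examples
#' global_align_identity("AAAA", "AATAA")  # 0.8
#' @export
global_align_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  check_dna(a, "a"); check_dna(b, "b")
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty input sequence")
  av <- s2c(a); bv <- s2c(b)
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1L, m + 1L)
  S[1L, ] <- gap * (0L:m)
  S[, 1L] <- gap * (0L:n)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],       # diagonal
                               S[i, j + 1L] + gap,     # up (gap in b)
                               S[i + 1L, j] + gap)     # left (gap in a)
    }
  }
  # high-road traceback: diagonal > up > left
  i <- n; j <- m
  matches <- 0L; columns <- 0L
  while (i > 0L || j > 0L) {
    columns <- columns + 1L
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      if (av[i] == bv[j] && av[i] != "N") matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  structure(matches / columns, score = S[n + 1L, m + 1L], columns = columns)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in all six frames
#'
#' Reports every ATG-to-stop ORF (stop codon included in the interval) of at
#' least `min_len` bp, on both strands, sorted by start position. Minus-strand
#' ORFs are reported in plus-strand coordinates with `strand = "-"`.
#'
#' @param s DNA string.
#' @param min_len Minimum ORF length in bp; must be a positive multiple of 3.
#' @return A list of [interval()]s (possibly empty).
#' @export
find_orfs <- function(s, min_len = 300L) {
  check_dna(s)
  min_len <- as.integer(min_len)
  if (min_len < 3L || min_len %% 3L != 0L)
    stop("min_len must be >= 3 and divisible by 3")
  L <- nchar(s)
  orfs <- list()
  scan_strand <- function(seq, strand) {
    for (off in 0:2) {
      starts <- seq(1L + off, L - 2L, by = 3L)
      if (length(starts) == 0L) next
      cods <- substring(seq, starts, starts + 2L)
      atg <- which(cods == "ATG")
      stp <- which(cods %in% STOP_CODONS)
      for (ai in atg) {
        nxt <- stp[stp >= ai]
        if (length(nxt) == 0L) next
        si <- nxt[1L]
        len <- (si - ai + 1L) * 3L
        if (len < min_len) next
        b1 <- starts[ai]; b2 <- starts[si] + 3L  # half-open
        if (strand == "+") {
          orfs[[length(orfs) + 1L]] <<- interval(b1, b2, "+")
        } else {
          orfs[[length(orfs) + 1L]] <<- interval(L - b2 + 2L, L - b1 + 2L, "-")
        }
      }
    }
  }
  if (L >= 3L) {
    scan_strand(s, "+")
    scan_strand(revcomp(s), "-")
  }
  ord <- order(vapply(orfs, `[[`, integer(1), "start"),
               vapply(orfs, `[[`, integer(1), "end"))
  orfs[ord]
}

#' Drop ORFs nested inside a longer ORF on the same strand
#'
#' @param orfs List of intervals from [find_orfs()].
#' @return Filtered list.
#' @export
maximal_orfs <- function(orfs) {
  if (length(orfs) <= 1L) return(orfs)
  keep <- rep(TRUE, length(orfs))
  for (i in seq_along(orfs)) {
    for (j in seq_along(orfs)) {
      if (i == j || !keep[i]) next
      if (orfs[[i]]$strand == orfs[[j]]$strand &&
          iv_contains(orfs[[j]], orfs[[i]]) &&
          interval_length(orfs[[j]]) > interval_length(orfs[[i]])) {
        keep[i] <- FALSE
      }
    }
  }
  orfs[keep]
}

CODON_TABLE <- {
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSRRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  cods <- paste0(rep(bases, each = 16L),
                 rep(rep(bases, each = 4L), 4L),
                 rep(bases, 16L))
  stats::setNames(aas, cods)
}

#' Translate a DNA string (frame 1) to amino acids
#'
#' @param s DNA string, length a multiple of 3; codons containing `N` become `X`.
#' @return Amino-acid string; stops are `*`.
#' @export
translate_dna <- function(s) {
  check_dna(s)
  if (nchar(s) %% 3L != 0L) stop("length must be a multiple of 3")
  starts <- seq(1L, nchar(s), by = 3L)
  cods <- substring(s, starts, starts + 2L)
  aa <- CODON_TABLE[cods]
  aa[is.na(aa)] <- "X"
  c2s(aa)
}
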