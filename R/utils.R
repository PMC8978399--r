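# internal helpers shared across modules

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' @noRd
s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' @noRd
c2s <- function(x) paste(x, collapse = "")

#' Validate a DNA string over {A,C,G,T,N}
#' @noRd
check_dna <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop(what, " must be a single character string", call. = FALSE)
  if (grepl("[^ACGTN]", s))
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  invisible(s)
}

#' Run code with a private RNG stream, restoring the caller's state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Round half up to one decimal (the convention used for fractional copy numbers)
#' @noRd
round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Rolling mean of a 0/1 vector over a fixed window, via cumulative sums
#' @noRd
roll_mean <- function(x, w) {
  n <- length(x)
  if (w > n) return(mean(x))
  cs <- cumsum(c(0, x))
  (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
}

#' Choose the copy phase of a periodic run by copy support
#'
#' Evaluates every offset in `[a, a + p - 1]`: for each, a copy grid is laid
#' over the supported region (extended one period on each side), a
#' majority-rule consensus is built, and the offset maximizing the summed
#' identity margin of its copies, `sum(max(0, identity - thr))`, wins
#' (ties: leftmost). This aligns copy boundaries with the true array
#' boundary: a rotated grid turns `n` true copies into `n - 1` full copies
#' plus two straddlers whose margin is at or near zero.
#'
#' `x` is the sequence as a character vector; positions that are not plain
#' bases (N, masks) never match.
#' @noRd
choose_phase <- function(x, a, R_end, p, thr) {
  xi <- match(x, c("A", "C", "G", "T"))
  xi[is.na(xi)] <- 0L
  L <- length(x)
  lo <- max(1L, a - p)
  hi <- min(L, R_end + p)
  best_o <- a; best_margin <- -1
  for (o in a:min(a + p - 1L, hi - p + 1L)) {
    first <- o - p * ((o - lo) %/% p)   # grid covers the whole region
    starts <- seq(first, hi - p + 1L, by = p)
    if (length(starts) < 2L) next
    M <- matrix(xi[rep(starts, each = p) + 0:(p - 1L)],
                nrow = length(starts), ncol = p, byrow = TRUE)
    counts <- vapply(1:4, function(b) colSums(M == b), numeric(p))
    cons <- max.col(counts, ties.method = "first")   # A<C<G<T tie order
    idn <- rowMeans(M == rep(cons, each = nrow(M)) & M != 0L)
    margin <- sum(pmax(0, idn - thr))
    if (margin > best_margin + 1e-9) { best_margin <- margin; best_o <- o }
  }
  best_o
}
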