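test_that("FASTA round trip preserves records, uppercases and maps U to T", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">one first record", "acgTAcgt", "ACGT",
               ">two", "uuagc"), fa)
  recs <- read_fasta(fa)
  expect_equal(names(recs), c("one", "two"))
  expect_equal(unname(nchar(recs)), c(12L, 5L))
  expect_equal(recs[["one"]], "ACGTACGTACGT")
  expect_equal(recs[["two"]], "TTAGC")

  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, out)
  expect_equal(read_fasta(out), recs)
})

test_that("empty or malformed FASTA is an explicit error", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), fa)
  expect_error(read_fasta(fa), "empty")
  writeLines(c(">x", "ACGTQQ"), fa)
  expect_error(read_fasta(fa), "non-ACGTN")
})

test_that("revcomp is a length-preserving involution with N fixed", {
  expect_equal(revcomp("CACTA"), "TAGTG")
  expect_equal(revcomp("N"), "N")
  expect_error(revcomp("ACGU"), "outside")
  for (i in 1:20) {
    s <- rand_seq(withr::with_seed(i, sample(5:80, 1)), i * 3)
    expect_identical(revcomp(revcomp(s)), s)
    expect_identical(nchar(revcomp(s)), nchar(s))
  }
})

test_that("ungapped identity is symmetric, bounded and prefix-aware", {
  expect_equal(ungapped_identity("ACGT", "ACGT"), 1.0)
  expect_equal(ungapped_identity("ACGT", "ACGA"), 0.75)
  expect_equal(ungapped_identity("ACGTAA", "ACGTTT", span = 4), 1.0)
  expect_error(ungapped_identity("ACG", "ACGT"), "span")
  # N counts as a mismatch even against N
  expect_equal(ungapped_identity("AN", "AN"), 0.5)
  for (i in 1:20) {
    a <- rand_seq(40, i); b <- rand_seq(40, i + 500)
    expect_equal(ungapped_identity(a, b), ungapped_identity(b, a))
    expect_gte(ungapped_identity(a, b), 0)
    expect_lte(ungapped_identity(a, b), 1)
  }
})

test_that("global alignment identity matches frozen examples and conventions", {
  expect_equal(as.numeric(global_align_identity("AAAA", "AATAA")), 0.8)
  expect_equal(as.numeric(global_align_identity("ACGT", "ACGT")), 1.0)
  expect_error(global_align_identity("", "A"), "empty")
  for (i in 1:10) {
    a <- rand_seq(25, i); b <- rand_seq(20, i + 100)
    expect_equal(as.numeric(global_align_identity(a, b)),
                 as.numeric(global_align_identity(b, a)))
  }
})

test_that("global alignment score equals the Biostrings optimum", {
  skip_if_not_installed("Biostrings")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:10) {
    a <- rand_seq(withr::with_seed(i, sample(5:40, 1)), i * 7)
    b <- rand_seq(withr::with_seed(i + 50, sample(5:40, 1)), i * 7 + 3)
    mine <- attr(global_align_identity(a, b), "score")
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2))
    expect_equal(mine, ref)
  }
})

test_that("alignment identity equals a brute-force enumeration on tiny strings", {
  # enumerate every global alignment recursively; oracle is the best
  # achievable score, independent of the package's DP
  enum_best <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    rec <- function(i, j) {
      if (i == 0 && j == 0) return(0)
      best <- -Inf
      if (i > 0 && j > 0)
        best <- max(best, rec(i - 1, j - 1) +
                      (if (substr(a, i, i) == substr(b, j, j)) match else mismatch))
      if (i > 0) best <- max(best, rec(i - 1, j) + gap)
      if (j > 0) best <- max(best, rec(i, j - 1) + gap)
      best
    }
    rec(nchar(a), nchar(b))
  }
  for (i in 1:12) {
    a <- rand_seq(withr::with_seed(i, sample(1:5, 1)), i * 13)
    b <- rand_seq(withr::with_seed(i + 30, sample(1:5, 1)), i * 13 + 5)
    expect_equal(attr(global_align_identity(a, b), "score"), enum_best(a, b),
                 info = paste(a, b))
  }
})

test_that("ORF finding matches a per-frame oracle on random sequences", {
  orfs <- find_orfs("ATGAAATAA", min_len = 9L)
  expect_length(orfs, 1L)
  expect_equal(orfs[[1]]$start, 1L)
  expect_equal(interval_length(orfs[[1]]), 9L)
  expect_equal(orfs[[1]]$strand, "+")
  expect_equal(find_orfs("CCCCCCCCC", min_len = 3L), list())

  oracle <- function(s, min_len) {
    hits <- list()
    scan <- function(seq, minus) {
      L <- nchar(seq)
      for (off in 0:2) {
        i <- 1 + off
        while (i + 2 <= L) {
          if (substr(seq, i, i + 2) == "ATG") {
            j <- i
            while (j + 2 <= L) {
              cod <- substr(seq, j, j + 2)
              if (cod %in% c("TAA", "TAG", "TGA")) {
                len <- j + 3 - i
                if (len >= min_len) {
                  iv <- if (!minus) c(i, i + len) else c(L - (i + len) + 2, L - i + 2)
                  hits[[length(hits) + 1]] <<- c(iv, if (minus) -1 else 1)
                }
                break
              }
              j <- j + 3
            }
          }
          i <- i + 3
        }
      }
    }
    scan(s, FALSE); scan(revcomp(s), TRUE)
    if (length(hits) == 0) return(matrix(numeric(0), ncol = 3))
    m <- do.call(rbind, hits)
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  for (i in 1:8) {
    s <- rand_seq(2000, i * 19)
    got <- find_orfs(s, min_len = 300L)
    gm <- do.call(rbind, lapply(got, function(iv)
      c(iv$start, iv$end, if (iv$strand == "-") -1 else 1)))
    if (is.null(gm)) gm <- matrix(numeric(0), ncol = 3)
    expect_equal(unname(gm), unname(oracle(s, 300L)), info = paste("seed", i))
  }
})

test_that("interval arithmetic reproduces printed-coordinate subtraction", {
  expect_equal(interval_length(interval(10098, 15648)), 5550L)
  expect_equal(interval_length(interval(7, 7)), 0L)
  expect_equal(interval_length(interval(3254, 3457)), 203L)
  expect_error(interval(10, 5), "end")
})

test_that("GFF3 and BED writers use the documented coordinate conversions", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(data.frame(seqid = "c1", source = "x", type = "region",
                        start = 10L, end = 20L, score = ".", strand = "+",
                        phase = ".", attributes = "ID=a"), gff)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  expect_match(lines[2], "\t10\t19\t")   # half-open 20 -> inclusive 19

  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed("c1", list(interval(10, 20)), "a", bed)
  expect_match(readLines(bed), "\t9\t19\t")
})
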