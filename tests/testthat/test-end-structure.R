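test_that("self dot-plot contains the diagonal and symmetric direct hits", {
  s <- rand_seq(120, 42)
  dp <- self_dotplot(s, word = 12)
  diag_hits <- dp[dp$a == dp$b, ]
  expect_equal(nrow(diag_hits), nchar(s) - 12 + 1)
  # direct-hit symmetry
  key <- paste(dp$a, dp$b); rkey <- paste(dp$b, dp$a)
  expect_true(all(rkey %in% key))
  # word = L: single full-diagonal hit
  dp_full <- self_dotplot(s, word = nchar(s))
  expect_equal(nrow(dp_full), 1L)
})

test_that("a tandem array shows direct off-diagonals at monomer multiples", {
  arr <- strrep(chenopodium_sat_monomer, 4)
  dp <- self_dotplot(arr, word = 30)
  offs <- unique(abs(dp$a - dp$b))
  expect_true(all(offs %% 171 == 0))
  expect_true(all(c(0, 171, 342) %in% offs))
})

test_that("inverted hits appear for inverted repeats and off-diagonal noise is near expectation", {
  tir <- rand_tir(5)
  s <- paste0(tir, rand_seq(200, 6), revcomp(tir))
  dp <- self_dotplot(s, word = nchar(tir), include_inverted = TRUE)
  inv <- dp[dp$orientation == "inverted", ]
  expect_true(any(inv$a == 1 & inv$b == nchar(s) - nchar(tir) + 1))
  # Bernoulli expectation for off-diagonal direct hits in random sequence
  s2 <- rand_seq(2000, 99)
  dp2 <- self_dotplot(s2, word = 12)
  n_off <- sum(dp2$a != dp2$b)
  npos <- (2000 - 12 + 1)
  expected <- npos * (npos - 1) * 4^-12
  sd <- sqrt(npos * (npos - 1) * 4^-12)
  expect_lte(abs(n_off - expected), 5 * sd + 1)
})

test_that("TIR detection recovers a perfectly mirrored terminus at its true length", {
  tir <- jozin_tirs[["pamiricum"]]
  # junction bases are fixed so the mirrored region provably stops at 28 bp
  s <- paste0(tir, "A", rand_seq(398, 11), "A", revcomp(tir))
  hit <- find_tir(s)
  expect_equal(hit$length, 28L)
  expect_equal(hit$pair_identity, 1.0)
  expect_true(hit$cacta_intact)
  expect_equal(hit$left_seq, tir)
  expect_equal(hit$right_seq, revcomp(tir))
})

test_that("TIR detection returns nothing without the CACTA anchor", {
  s <- paste0("GGGGG", rand_seq(400, 12))
  expect_null(find_tir(s))
  expect_error(find_tir("CACTAAA"), "shorter")
})

test_that("unit-length estimation finds exact and noisy periods", {
  expect_equal(as.integer(estimate_unit_length(strrep("TATTTGTAACTA", 10))), 12L)
  m15 <- rand_motif(15, 77)
  noisy <- mutate(strrep(m15, 8), 0.05, 3)
  expect_equal(as.integer(estimate_unit_length(noisy, c(10, 20))), 15L)
  # brute-force identity-vs-shift oracle agrees on the full curve
  win <- strrep(rand_motif(13, 21), 7)
  curve <- attr(estimate_unit_length(win, c(10, 20)), "curve")
  oracle <- vapply(10:20, function(p) {
    x <- strsplit(win, "")[[1]]; L <- length(x)
    mean(x[1:(L - p)] == x[(p + 1):L])
  }, numeric(1))
  expect_equal(unname(curve), oracle)
  expect_error(estimate_unit_length("ACGT"), "too short")
})

test_that("subTIR annotation recovers constructed per-end copy counts", {
  m <- rand_motif(12, 501)
  tir <- rand_tir(502)
  s <- paste0(tir, strrep(m, 5), rand_seq(1500, 503),
              revcomp(strrep(m, 5)), revcomp(tir))
  st <- detect_subtir(s)
  expect_equal(st$n_5prime, 5L)
  expect_equal(st$n_3prime, 5L)
  expect_equal(st$n_total, 10L)
  expect_equal(st$unit_length, 12L)
  expect_true(all(st$copies$identity == 1))
  expect_equal(nrow(st$copies), st$n_total)
  # one substitution per copy (11/12 ~ 91.7%) stays above the 0.80 threshold
  mut_copy <- function(cp, k) {
    b <- substr(cp, k, k)
    sub <- setdiff(c("A", "C", "G", "T"), b)[1]
    paste0(substr(cp, 1, k - 1), sub, substr(cp, k + 1, nchar(cp)))
  }
  copies5 <- paste(vapply(1:5, function(k) mut_copy(m, 2 * k), ""), collapse = "")
  s2 <- paste0(tir, copies5, rand_seq(1500, 504),
               revcomp(copies5), revcomp(tir))
  st2 <- detect_subtir(s2)
  expect_equal(st2$n_total, 10L)
})

test_that("subTIR annotation returns an empty result on plain random sequence", {
  st <- detect_subtir(rand_seq(2500, 321))
  expect_equal(st$n_total, 0L)
})

test_that("TSD check recognizes flanking duplications", {
  contig <- paste0(rand_seq(50, 61), "TAC", rand_seq(200, 62), "TAC",
                   rand_seq(50, 63))
  span <- interval(54, 254)
  expect_equal(check_tsd(contig, span), "TAC")
  contig2 <- paste0(rand_seq(50, 61), "TAC", rand_seq(200, 62), "GGA",
                    rand_seq(50, 63))
  expect_null(check_tsd(contig2, span))
  expect_error(check_tsd("ACGTACGT", interval(1, 6)), "flank")
})

test_that("element calling classifies complete, subtir-only and incomplete anchors", {
  # complete
  sp <- rand_element_spec(4)
  one <- embed_one(sp, 40)
  tp <- one$truth$domain_ivs[one$truth$domain_ivs$name == "Transposase_21", ]
  cm <- call_element(one$emb$seq, interval(tp$start, tp$end),
                     contig_id = one$emb$id)
  expect_equal(cm$completeness, "complete")
  expect_equal(cm$span$start, one$truth$span$start)
  expect_equal(cm$span$end, one$truth$span$end)
  expect_equal(cm$tsd, "ATG")

  # ablated TIR anchors, subTIR arrays intact
  sp2 <- rand_element_spec(5)
  sp2$ablate_tir <- TRUE
  one2 <- embed_one(sp2, 41)
  tp2 <- one2$truth$domain_ivs[one2$truth$domain_ivs$name == "Transposase_21", ]
  cm2 <- call_element(one2$emb$seq, interval(tp2$start, tp2$end),
                      contig_id = one2$emb$id)
  expect_equal(cm2$completeness, "subtir_only")
  expect_gte(cm2$subtir$n_5prime, 3L)
  expect_gte(cm2$subtir$n_3prime, 3L)
  # boundaries lie inside the constructed element (TIR stubs excluded)
  expect_gte(cm2$span$start, one2$truth$span$start)
  expect_lte(cm2$span$end, one2$truth$span$end)

  # anchor in plain background
  bg <- rand_seq(30000, 77)
  cm3 <- call_element(bg, interval(15000, 15630))
  expect_equal(cm3$completeness, "incomplete")
  expect_error(call_element(bg, interval(40000, 40630)), "outside")
})
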