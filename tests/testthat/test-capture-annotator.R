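test_that("captured fragments are placed relative to the TAD landmark", {
  el <- list(
    domains = data.frame(name = c("TAD", "Transposase_21"),
                         start = c(4211L, 5000L), end = c(4451L, 5630L)),
    coding_ivs = list(interval(4208, 7500)),
    span = interval(1, 10109))
  frags <- data.frame(label = c("Neprosin_pfam14365", "Neprosin_pfam03080"),
                      start = c(2894L, 3254L), end = c(3007L, 3457L))
  ann <- annotate_capture(el, frags)
  expect_equal(ann$dist_to_tad, c(1204L, 754L))
  expect_equal(ann$element_region, c("five_prime", "five_prime"))
  expect_false(any(ann$in_coding))

  # AP2-style fragment 857 bp upstream
  ap2 <- data.frame(label = "AP2", start = 4211L - 857L - 80L,
                    end = 4211L - 857L)
  ann2 <- annotate_capture(el, ap2)
  expect_equal(ann2$dist_to_tad, 857L)
  expect_equal(ann2$element_region, "five_prime")

  # fragment inside the coding interval
  incod <- data.frame(label = "x", start = 5000L, end = 5100L)
  ann3 <- annotate_capture(el, incod)
  expect_true(ann3$in_coding)
  expect_equal(ann3$element_region, "internal")

  el_notad <- el; el_notad$domains <- el$domains[-1, ]
  expect_error(annotate_capture(el_notad, frags), "TAD")
})

test_that("monomer consensus is the per-column majority with fixed tie order", {
  expect_equal(build_monomer_consensus(c("ACGT", "ACGT", "ACGT")), "ACGT")
  expect_equal(build_monomer_consensus(c("AA", "AC", "AC")), "AC")
  expect_equal(build_monomer_consensus(c("AT", "TA")), "AA")  # ties: A first
  expect_error(build_monomer_consensus(c("AC", "A")), "length")
  expect_error(build_monomer_consensus(character()), "no copies")
})

test_that("monomer consensus equals a brute-force tally on exhaustive tiny inputs", {
  oracle <- function(copies) {
    mat <- do.call(rbind, strsplit(copies, ""))
    paste(apply(mat, 2, function(col) {
      tab <- sapply(c("A", "C", "G", "T", "N"), function(b) sum(col == b))
      names(tab)[which.max(tab)]
    }), collapse = "")
  }
  bases <- c("A", "C", "G", "T")
  # all 3-copy sets of length-2 strings over a 2-letter alphabet, plus
  # seeded random cases over the full alphabet
  two <- apply(expand.grid(c("A", "C"), c("A", "C")), 1, paste, collapse = "")
  for (i in seq_along(two)) for (j in seq_along(two)) for (k in seq_along(two)) {
    cps <- c(two[i], two[j], two[k])
    expect_equal(build_monomer_consensus(cps), oracle(cps))
  }
  for (r in 1:25) {
    cps <- withr::with_seed(r, replicate(
      sample(2:5, 1), paste(sample(bases, 6, replace = TRUE), collapse = "")))
    expect_equal(build_monomer_consensus(cps), oracle(cps), info = paste(r))
  }
})

test_that("noisy monomer copies still vote out the original consensus", {
  mono <- chenopodium_sat_monomer
  copies <- vapply(1:50, function(k) mutate(mono, 0.05, k), character(1))
  expect_equal(build_monomer_consensus(copies), mono)
})

test_that("tandem array detection is exact on clean constructions", {
  m40 <- rand_seq(40, 91, gc = 0.5)
  arr <- detect_tandem_array(strrep(m40, 10))
  expect_length(arr, 1L)
  expect_equal(arr[[1]]$monomer_len, 40L)
  expect_equal(arr[[1]]$copy_number, 10.0)
  expect_equal(arr[[1]]$mean_copy_identity, 1.0)
  expect_equal(arr[[1]]$consensus, m40)

  # truncated final copy gives a fractional copy number
  s <- substr(strrep(chenopodium_sat_monomer, 33), 1, 5550)
  arr2 <- detect_tandem_array(s)
  expect_equal(arr2[[1]]$monomer_len, 171L)
  expect_equal(arr2[[1]]$copy_number, 32.5)
  expect_equal(interval_length(arr2[[1]]$iv), 5550L)
})

test_that("array detection recovers monomer and copies inside flanked noisy sequence", {
  mono <- rand_seq(171, 15, gc = 0.5)
  core <- mutate(strrep(mono, 20), 0.02, 8)
  s <- paste0(rand_seq(1500, 16), core, rand_seq(1500, 17))
  arr <- detect_tandem_array(s)
  expect_length(arr, 1L)
  expect_equal(arr[[1]]$monomer_len, 171L)
  expect_equal(arr[[1]]$copy_number, 20.0, tolerance = 0.5 / 20)
  # consensus equals the original monomer (majority vote over 20 copies)
  expect_equal(arr[[1]]$consensus, mono)
  expect_equal(detect_tandem_array(rand_seq(3000, 18)), list())
})

test_that("array detection property: random monomers, sizes and noise", {
  ok_mono <- 0; ok_cn <- 0; n_rep <- 40
  for (i in 1:n_rep) {
    par <- withr::with_seed(i * 7 + 1, list(
      ml = sample(30:400, 1), cp = sample(3:40, 1) + sample(0:9, 1) / 10,
      mu = runif(1, 0, 0.05)))
    mono <- rand_seq(par$ml, i * 11, gc = 0.5)
    total <- round(par$cp * par$ml)
    core <- mutate(substr(strrep(mono, ceiling(par$cp) + 1), 1, total),
                   par$mu, i * 13)
    s <- paste0(rand_seq(800, i * 17), core, rand_seq(800, i * 19))
    arr <- detect_tandem_array(s)
    if (length(arr) >= 1) {
      best <- arr[[which.max(vapply(arr, function(a)
        interval_length(a$iv), integer(1)))]]
      if (best$monomer_len == par$ml) ok_mono <- ok_mono + 1
      if (abs(best$copy_number - round(total / par$ml, 1)) <= 0.5)
        ok_cn <- ok_cn + 1
    }
  }
  expect_gte(ok_mono / n_rep, 0.95)
  expect_gte(ok_cn / n_rep, 0.95)
})

test_that("fractional copy-number consistency holds for detected arrays", {
  for (i in 1:5) {
    mono <- rand_seq(withr::with_seed(i, sample(40:200, 1)), i * 23, gc = 0.5)
    total <- withr::with_seed(i + 10, sample(400:2000, 1))
    s <- substr(strrep(mono, ceiling(total / nchar(mono)) + 1), 1, total)
    arr <- detect_tandem_array(s)
    expect_length(arr, 1L)
    a <- arr[[1]]
    expect_lt(abs(a$copy_number * a$monomer_len - interval_length(a$iv)),
              a$monomer_len)
  }
})

test_that("arrays are located relative to the coding region", {
  el <- list(span = interval(1, 16524),   # element of length 16523
             coding_ivs = list(interval(1676, 9409)))
  res <- locate_array_in_element(el, list(iv = interval(10098, 15648)))
  expect_equal(res$region, "three_prime")
  expect_equal(res$dist_to_3prime, 16523L + 1L - 15648L)
  expect_equal(locate_array_in_element(
    el, list(iv = interval(100, 1200)))$region, "five_prime")
  over <- locate_array_in_element(el, list(iv = interval(9000, 9600)))
  expect_equal(over$region, "internal")
  expect_true(over$flagged)
  expect_error(locate_array_in_element(el, list(iv = interval(16000, 17000))),
               "outside")
})
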