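test_that("protein p-distance counts differing sites over comparable sites", {
  expect_equal(p_distance_protein("MKV", "MKV"), 0)
  expect_equal(p_distance_protein("AC", "AD"), 0.5)
  expect_equal(p_distance_protein("A-C", "ADC"), 0)   # gap column excluded
  expect_error(p_distance_protein("--", "AA"), "comparable")
  aas <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K")
  for (i in 1:10) {
    pair <- withr::with_seed(i, list(a = sample(aas, 100, TRUE),
                                     b = sample(aas, 100, TRUE)))
    oracle <- mean(pair$a != pair$b)
    expect_equal(p_distance_protein(paste(pair$a, collapse = ""),
                                    paste(pair$b, collapse = "")), oracle)
  }
})

test_that("Tamura 1992 distance matches ape and the closed form", {
  skip_if_not_installed("ape")
  for (k in 1:8) {
    a <- rand_seq(300, k * 31, gc = 0.55)
    b <- mutate(a, 0.1, k * 37)
    bin <- ape::as.DNAbin(t(sapply(list(a, b), function(s) strsplit(s, "")[[1]])))
    expect_equal(as.numeric(t92_distance(a, b)),
                 as.numeric(ape::dist.dna(bin, model = "T92")),
                 tolerance = 1e-12)
  }
  expect_equal(as.numeric(t92_distance("ACGT", "ACGT")), 0)
})

test_that("Tamura 1992 equals its closed form for chosen P, Q, GC", {
  # build a pair with known transition/transversion proportions:
  # 200 sites, 20 transitions (A<->G), 10 transversions (A<->C), theta known
  a <- paste(rep(c("A", "C", "G", "T"), each = 50), collapse = "")
  bv <- strsplit(a, "")[[1]]
  bv[1:20] <- "G"     # 20 A->G transitions
  bv[21:30] <- "C"    # 10 A->C transversions
  b <- paste(bv, collapse = "")
  P <- 20 / 200; Q <- 10 / 200
  theta <- mean(c(strsplit(a, "")[[1]], bv) %in% c("G", "C"))
  h <- 2 * theta * (1 - theta)
  d_exp <- -h * log(1 - P / h - Q) - 0.5 * (1 - h) * log(1 - 2 * Q)
  expect_equal(as.numeric(t92_distance(a, b)), d_exp)
  # continuous-gamma variant replaces -log(x) by a*(x^(-1/a) - 1)
  g <- 0.5
  d_gam <- h * g * ((1 - P / h - Q)^(-1 / g) - 1) +
    0.5 * (1 - h) * g * ((1 - 2 * Q)^(-1 / g) - 1)
  expect_equal(as.numeric(t92_distance(a, b, gamma_shape = g)), d_gam)
  expect_gte(d_gam, d_exp)   # gamma correction inflates distances
})

test_that("T92 reduces toward Kimura behaviour at GC 0.5 and flags saturation", {
  skip_if_not_installed("ape")
  a <- strrep("ACGT", 100)
  b <- mutate(a, 0.12, 5)
  bin <- ape::as.DNAbin(t(sapply(list(a, b), function(s) strsplit(s, "")[[1]])))
  # theta drifts marginally from 0.5 under mutation, hence the loose bound
  expect_equal(as.numeric(t92_distance(a, b)),
               as.numeric(ape::dist.dna(bin, model = "K80")), tolerance = 1e-5)
  # saturated pair: transversions at half of all sites
  av <- rep(c("A", "C"), 100)
  bv <- rep(c("C", "A"), 100)
  d <- t92_distance(paste(av, collapse = ""), paste(bv, collapse = ""))
  expect_true(is.nan(as.numeric(d)))
  expect_true(attr(d, "saturated"))
})

test_that("t92 dominates the raw p-distance on unsaturated pairs", {
  for (k in 1:10) {
    a <- rand_seq(400, k * 3, gc = 0.5)
    b <- mutate(a, withr::with_seed(k, runif(1, 0.01, 0.2)), k * 7)
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    pd <- mean(av != bv)
    expect_gte(as.numeric(t92_distance(a, b)) + 1e-12, pd)
  }
})

test_that("distance matrices are symmetric with zero diagonal", {
  seqs <- two_family_seqs(3, len = 300, seed = 4)
  d <- distance_matrix(seqs, "t92")
  expect_equal(d, t(d), ignore_attr = TRUE)
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_equal(d["fam1_1", "fam1_2"],
               as.numeric(t92_distance(seqs[["fam1_1"]], seqs[["fam1_2"]])))
  expect_error(distance_matrix(c(a = "ACGT", b = "ACG")), "ragged")
  expect_error(distance_matrix(c(a = "ACGT")), "at least 2")
})

test_that("neighbor joining exactly recovers additive 4- and 5-taxon metrics", {
  skip_if_not_installed("ape")
  for (k in 1:50) {
    tre <- withr::with_seed(k, ape::rtree(if (k %% 2) 4 else 5))
    d <- ape::cophenetic.phylo(tre)
    nwk <- nj_tree(d)
    back <- ape::cophenetic.phylo(ape::read.tree(text = nwk))
    expect_lt(max(abs(back[rownames(d), colnames(d)] - d)), 1e-8)
  }
  # the ((A,B),(C,D)) example, written as an explicit additive matrix
  d4 <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 2,
                 6, 6, 2, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- ape::read.tree(text = nj_tree(d4))
  # A+B form a cherry, as do C+D
  pair <- function(t, x, y) {
    m <- ape::cophenetic.phylo(t)
    which.min(m[x, setdiff(colnames(m), x)]) == match(y, setdiff(colnames(m), x))
  }
  expect_true(pair(tr, "A", "B"))
  expect_true(pair(tr, "C", "D"))
  expect_error(nj_tree(d4[1:2, 1:2]), "at least 3")
})

test_that("saturated taxa are excluded from trees with a warning", {
  seqs <- two_family_seqs(2, len = 200, seed = 9)
  d <- distance_matrix(seqs, "t92")
  sat <- attr(d, "saturated")
  sat["fam1_1", "fam2_2"] <- sat["fam2_2", "fam1_1"] <- TRUE
  d[is.na(d)] <- 0
  d["fam1_1", "fam2_2"] <- d["fam2_2", "fam1_1"] <- NaN
  attr(d, "saturated") <- sat
  expect_warning(nwk <- nj_tree(d), "saturated")
  expect_false(grepl("fam2_2", nwk) && grepl("fam1_1", nwk))
})

test_that("clade assignment follows the nearest reference with a cutoff", {
  seqs <- two_family_seqs(4, len = 630, seed = 6)
  refs <- data.frame(label = c("fam1_1", "fam1_2", "fam2_1", "fam2_2"),
                     clade = c("cladeI", "cladeI", "cladeII", "cladeII"),
                     seq = unname(seqs[c("fam1_1", "fam1_2", "fam2_1", "fam2_2")]))
  hit <- assign_clade(seqs["fam1_3"], refs, "t92", cutoff = 0.5)
  expect_equal(hit$clade, "cladeI")
  hit2 <- assign_clade(seqs["fam2_3"], refs, "t92", cutoff = 0.5)
  expect_equal(hit2$clade, "cladeII")
  # identical to a reference: distance zero
  hit3 <- assign_clade(seqs["fam1_1"], refs, "t92", cutoff = 0.5)
  expect_equal(hit3$distance, 0)
  expect_equal(hit3$clade, "cladeI")
  # beyond the cutoff: unassigned
  far <- stats::setNames(rand_seq(630, 999), "far")
  hit4 <- assign_clade(far, refs, "t92", cutoff = 0.1)
  expect_equal(hit4$clade, "unassigned")
  expect_error(assign_clade(seqs["fam1_3"], refs[1:2, ], "t92"), "both clades")
})
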