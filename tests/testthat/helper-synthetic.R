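# Shared generators for property-style tests. All draws are seeded by the
# caller; nothing here touches the global RNG stream unseeded.

rand_seq <- function(len, seed, gc = 0.45) {
  stopifnot(is.numeric(seed))
  out <- withr::with_seed(seed, paste(
    sample(c("A", "T", "G", "C"), len, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
    collapse = ""))
  out
}

# a usable subTIR unit motif: no CACTA/TAGTG anchor strings across unit
# junctions (those would mimic TIR anchors) and no strong rotational
# self-similarity (which would make the unit decomposition ambiguous)
rand_motif <- function(p, seed) {
  repeat {
    m <- rand_seq(p, seed)
    seed <- seed + 1000
    if (grepl("CACTA", strrep(m, 2), fixed = TRUE)) next
    if (grepl("TAGTG", strrep(revcomp(m), 2), fixed = TRUE)) next
    x <- strsplit(strrep(m, 2), "")[[1]]
    selfsim <- vapply(1:(p - 1), function(d) mean(x[1:p] == x[(d + 1):(d + p)]),
                      numeric(1))
    if (max(selfsim) < 0.7) return(m)
  }
}

rand_tir <- function(seed) paste0("CACTA", rand_seq(23, seed + 7))

# one random element spec drawn under a fixed seed
rand_element_spec <- function(i, mut_rate = 0, with_array = FALSE,
                              n5 = NULL, n3 = NULL, unit_len = NULL) {
  draws <- withr::with_seed(i * 101 + 17, list(
    p = sample(10:20, 1), n5 = sample(3:15, 1), n3 = sample(3:15, 1),
    cda = sample(4, 1)))
  p <- if (is.null(unit_len)) draws$p else unit_len
  orf2 <- list(character(), "Peptidase_C48", "Transposase_24",
               c("Transposase_24", "Peptidase_C48"))[[draws$cda]]
  element_spec(
    tir = rand_tir(i * 31), subtir_motif = rand_motif(p, i * 53),
    n5 = if (is.null(n5)) draws$n5 else n5,
    n3 = if (is.null(n3)) draws$n3 else n3,
    orf2_domains = orf2,
    sat_array = if (with_array)
      list(monomer = rand_seq(80, i * 91, gc = 0.5), copies = 6.5),
    tsd = "ATG", mut_rate = mut_rate, seed = i)
}

# build, embed in background and return (embedded, truth of the one element)
embed_one <- function(spec, seed) {
  el <- build_element(spec)
  emb <- embed_in_background(list(el), bg_len = 2 * el$truth$length + 10000,
                             gc = 0.4, seed = seed)
  list(emb = emb, truth = emb$truth[[1]])
}

# substitute a fraction of positions with a different base; unlike the
# generator's noise model this is not capped, so family ancestors can be
# diverged arbitrarily far
diverge_seq <- function(s, rate, seed) {
  withr::with_seed(seed, {
    x <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(x)) < rate)
    x[hit] <- vapply(x[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(x, collapse = "")
  })
}

# aligned two-family DNA set: two diverged ancestors, members lightly mutated
two_family_seqs <- function(n_per_family, len = 630, anc_div = 0.4,
                            within = 0.03, seed = 1) {
  anc1 <- rand_seq(len, seed * 11)
  anc2 <- diverge_seq(anc1, anc_div, seed * 13)
  seqs <- c(
    stats::setNames(
      lapply(seq_len(n_per_family), function(k) mutate(anc1, within, seed * 7 + k)),
      paste0("fam1_", seq_len(n_per_family))),
    stats::setNames(
      lapply(seq_len(n_per_family), function(k) mutate(anc2, within, seed * 5 + k)),
      paste0("fam2_", seq_len(n_per_family))))
  unlist(seqs)
}
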