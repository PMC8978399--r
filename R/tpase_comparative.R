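# Transposase comparative analysis: pairwise distances, neighbor-joining
# trees and nearest-reference clade assignment.

#' Protein p-distance between two aligned sequences
#'
#' Columns where either sequence carries a gap (`-`) or `X` are excluded
#' pairwise; the distance is differing sites over compared sites.
#'
#' @param a,b Aligned amino-acid strings of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
p_distance_protein <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  av <- s2c(toupper(a)); bv <- s2c(toupper(b))
  use <- !(av %in% c("-", "X", ".")) & !(bv %in% c("-", "X", "."))
  if (!any(use)) stop("no comparable sites")
  mean(av[use] != bv[use])
}

#' Tamura (1992) three-parameter distance
#'
#' Corrects the observed transition (`P`) and transversion (`Q`) proportions
#' for multiple hits while accounting for GC-content bias, with
#' `theta` the mean GC fraction of the two sequences over compared sites and
#' `h = 2 theta (1 - theta)`:
#' `d = -h log(1 - P/h - Q) - (1 - h)/2 log(1 - 2 Q)`.
#' With `gamma_shape = a`, the continuous-gamma rate variant replaces each
#' `-log(x)` by `a (x^(-1/a) - 1)`. Sites where either sequence is not a
#' plain base are excluded pairwise. When a log argument is non-positive the
#' distance is saturated: `NaN` is returned with attribute
#' `saturated = TRUE` rather than an error, so callers can flag and exclude.
#'
#' @param a,b Aligned DNA strings of equal length.
#' @param gamma_shape Optional gamma shape parameter for among-site rate
#'   variation.
#' @return Non-negative distance (0 for identical sequences), with attribute
#'   `saturated` (logical).
#' @export
t92_distance <- function(a, b, gamma_shape = NULL) {
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  av <- s2c(toupper(a)); bv <- s2c(toupper(b))
  use <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  n <- sum(use)
  if (n == 0L) stop("no comparable sites")
  av <- av[use]; bv <- bv[use]
  theta <- mean(c(av, bv) %in% c("G", "C"))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  diff <- av != bv
  transition <- diff & (purine[av] == purine[bv])
  P <- mean(transition)
  Q <- mean(diff & !transition)
  h <- 2 * theta * (1 - theta)
  arg1 <- 1 - P / h - Q
  arg2 <- 1 - 2 * Q
  if (h == 0) arg1 <- arg2  # no GC heterozygosity: transitions unobservable
  if (arg1 <= 0 || arg2 <= 0)
    return(structure(NaN, saturated = TRUE))
  d <- if (is.null(gamma_shape)) {
    -h * log(arg1) - 0.5 * (1 - h) * log(arg2)
  } else {
    a_ <- gamma_shape
    h * a_ * (arg1^(-1 / a_) - 1) + 0.5 * (1 - h) * a_ * (arg2^(-1 / a_) - 1)
  }
  structure(max(d, 0), saturated = FALSE)
}

#' Pairwise distance matrix under a chosen model
#'
#' @param seqs Named character vector of pre-aligned sequences (protein for
#'   `"p_protein"`, DNA for `"t92"`). All must be the same length.
#' @param model `"p_protein"` or `"t92"`.
#' @param gamma_shape Optional gamma shape, `t92` only.
#' @return Symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames; attribute `"saturated"` is a logical matrix marking
#'   flagged (NaN) entries.
#' @export
distance_matrix <- function(seqs, model = c("t92", "p_protein"),
                            gamma_shape = NULL) {
  model <- match.arg(model)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences differ in length")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- if (model == "t92") t92_distance(seqs[[i]], seqs[[j]], gamma_shape)
    else p_distance_protein(seqs[[i]], seqs[[j]])
    d[i, j] <- d[j, i] <- as.numeric(dij)
    if (isTRUE(attr(dij, "saturated"))) sat[i, j] <- sat[j, i] <- TRUE
  }
  structure(d, saturated = sat)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}), returned as an unrooted Newick
#' string with branch lengths. Taxa with saturated (NaN) distances are
#' excluded with a warning rather than clipped.
#'
#' @param m Matrix from [distance_matrix()] (or any symmetric matrix with
#'   dimnames).
#' @return Newick string.
#' @export
nj_tree <- function(m) {
  sat <- attr(m, "saturated")
  if (!is.null(sat) && any(sat)) {
    drop <- names(which(rowSums(sat) > 0))
    # drop greedily the taxon involved in most saturated pairs
    while (any(sat)) {
      worst <- names(which.max(rowSums(sat)))
      keep <- setdiff(rownames(sat), worst)
      sat <- sat[keep, keep, drop = FALSE]
      m <- m[keep, keep, drop = FALSE]
    }
    warning("excluded taxa with saturated distances: ",
            paste(drop, collapse = ", "))
  }
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(as.matrix(m))
  ape::write.tree(tree)
}

#' Assign a query sequence to a clade by nearest reference
#'
#' @param query Named character vector of length 1, aligned to the
#'   references.
#' @param references data.frame with columns `label`, `clade`, `seq`.
#' @param model `"t92"` or `"p_protein"`.
#' @param cutoff Maximum distance to the nearest reference; beyond it the
#'   query is `"unassigned"`.
#' @return List with `query_label`, `clade`, `nearest_reference`,
#'   `distance`.
#' @export
assign_clade <- function(query, references, model = c("t92", "p_protein"),
                         cutoff = 0.5) {
  model <- match.arg(model)
  if (nrow(references) == 0L) stop("no references")
  if (length(unique(references$clade)) < 2L)
    stop("both clades must be represented among the references")
  dist_fun <- if (model == "t92") function(a, b) as.numeric(t92_distance(a, b))
  else p_distance_protein
  d <- vapply(references$seq, dist_fun, numeric(1), a = query[[1L]],
              USE.NAMES = FALSE)
  d[is.nan(d)] <- Inf
  k <- which.min(d)
  if (d[k] <= cutoff) {
    list(query_label = names(query)[1L], clade = references$clade[k],
         nearest_reference = references$label[k], distance = d[k])
  } else {
    list(query_label = names(query)[1L], clade = "unassigned",
         nearest_reference = references$label[k], distance = d[k])
  }
}

#' Write a distance matrix as a PHYLIP-style square matrix
#'
#' @param m Distance matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(formatC(rownames(m)[i], width = -10),
                     paste(sprintf("%.6f", m[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
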