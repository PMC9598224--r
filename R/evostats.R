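# Population-genetic and distance statistics.
#
# Tajima's D is computed from the standard coefficient chain (a1, a2, b1,
# b2, c1, c2, e1, e2) on gap-free columns, with significance from the
# conventional beta approximation. The transition/transversion bias uses
# closed-form pairwise Tamura-Nei rate-ratio estimates (k1 for purines, k2
# for pyrimidines) pooled across sequence pairs after a site-coverage
# filter. Distance matrices are Tamura-Nei (TN93) and trees are
# neighbor-joining; both delegate to ape behind this module's surface.

# columns usable for population-genetic statistics: unambiguous, gap-free
.complete_columns <- function(mat) {
  ok <- apply(mat, 2L, function(col) all(col %in% .BASES))
  mat[, ok, drop = FALSE]
}

.as_alignment_matrix <- function(alig) {
  mat <- if (inherits(alig, "gene_alignment")) alig$matrix else as.matrix(alig)
  matrix(toupper(mat), nrow = nrow(mat), dimnames = dimnames(mat))
}

#' Tajima's D neutrality test
#'
#' @param alig a `gene_alignment` or character matrix (rows = sequences).
#'   Columns containing gaps or ambiguity codes are excluded (complete
#'   deletion) before counting segregating sites.
#' @return a `tajima_result`: `n`, `S`, `pi` (mean pairwise differences),
#'   `theta_w`, `D` (NA when `S = 0`), `p_value` and `significant` at the
#'   two-tailed 0.05 level under the beta approximation.
#' @export
tajima_d <- function(alig) {
  mat <- .complete_columns(.as_alignment_matrix(alig))
  n <- nrow(mat)
  if (n < 4L) stop("Tajima's D requires at least 4 sequences")
  S <- sum(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  if (S == 0L) {
    return(structure(list(n = n, S = 0L, pi = 0, theta_w = 0, D = NA_real_,
                          p_value = NA_real_, significant = FALSE),
                     class = "tajima_result"))
  }
  # mean pairwise differences
  pi_sum <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pi_sum <- pi_sum + sum(mat[i, ] != mat[j, ])
  }
  pi <- pi_sum / choose(n, 2)

  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  theta_w <- S / a1
  D <- (pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))

  # beta approximation to the null distribution of D (mean 0, variance 1,
  # support [Dmin, Dmax])
  dmin <- (2 / n - 1 / a1) / sqrt(e2)
  dmax <- ((n + 1) / (2 * n) - 1 / a1) / sqrt(e2)
  rng <- dmax - dmin
  mu <- -dmin / rng
  s2 <- 1 / rng^2
  al <- mu * (mu * (1 - mu) / s2 - 1)
  be <- (1 - mu) * (mu * (1 - mu) / s2 - 1)
  x <- min(max((D - dmin) / rng, 0), 1)
  p <- if (al > 0 && be > 0) {
    2 * min(stats::pbeta(x, al, be), 1 - stats::pbeta(x, al, be))
  } else NA_real_
  structure(list(n = n, S = S, pi = pi, theta_w = theta_w, D = D,
                 p_value = p, significant = isTRUE(p < 0.05)),
            class = "tajima_result")
}

#' @export
print.tajima_result <- function(x, ...) {
  cat("Tajima's D: n =", x$n, " S =", x$S, "\n")
  cat(sprintf("  pi = %.4f  theta_W = %.4f  D = %s  p = %s%s\n",
              x$pi, x$theta_w,
              ifelse(is.na(x$D), "NA", sprintf("%.4f", x$D)),
              ifelse(is.na(x$p_value), "NA", sprintf("%.4f", x$p_value)),
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Tamura-Nei transition/transversion bias
#'
#' Columns are retained when at least `coverage_cutoff` of the rows carry an
#' unambiguous base (partial deletion). For every sequence pair the observed
#' proportions of purine transitions (P1), pyrimidine transitions (P2) and
#' transversions (Q) give closed-form Tamura-Nei rate-ratio estimates
#' k1 = (a1 - gY b)/(gR b) and k2 = (a2 - gR b)/(gY b), with
#' a1 = -log(1 - gR P1 / (2 gA gG) - Q / (2 gR)),
#' a2 = -log(1 - gY P2 / (2 gC gT) - Q / (2 gY)),
#' b = -log(1 - Q / (2 gR gY)). The overall bias is
#' R = (gA gG k1 + gT gC k2) / (gR gY), averaged over pairs weighted by the
#' number of sites compared. Saturated pairs (non-positive log argument) and
#' transversion-free pairs are skipped with a warning; negative sampling
#' fluctuations of k1/k2 are truncated at zero.
#'
#' @param alig a `gene_alignment` or character matrix.
#' @param coverage_cutoff minimum fraction of unambiguous rows per column.
#' @return a `tstv_bias`: `base_freqs`, `k_purines`, `k_pyrimidines`, `R`
#'   (NA when no substitutions survive the filter), `sites_used`,
#'   `pairs_used`.
#' @export
tstv_bias <- function(alig, coverage_cutoff = 0.95) {
  mat <- .as_alignment_matrix(alig)
  if (nrow(mat) < 2L) stop("need at least 2 sequences")
  cover <- colMeans(matrix(mat %in% .BASES, nrow = nrow(mat)))
  mat <- mat[, cover >= coverage_cutoff, drop = FALSE]
  sites_used <- ncol(mat)
  cells <- mat[mat %in% .BASES]
  f <- table(factor(cells, levels = .BASES)) / length(cells)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT

  n <- nrow(mat)
  k1s <- k2s <- Rs <- Ls <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- mat[i, ] %in% .BASES & mat[j, ] %in% .BASES
    a <- mat[i, use]; b <- mat[j, use]
    L <- length(a)
    if (!L) next
    diff <- a != b
    if (!any(diff)) next                       # identical pair: no information
    ts <- is_transition(a[diff], b[diff])
    pur <- a[diff] %in% .PURINES
    P1 <- sum(ts & pur) / L
    P2 <- sum(ts & !pur) / L
    Q <- sum(!ts) / L
    if (Q == 0) { skipped <- skipped + 1L; next }   # k undefined without tv
    w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
    w2 <- 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY)
    w3 <- 1 - Q / (2 * gR * gY)
    if (w1 <= 0 || w2 <= 0 || w3 <= 0) { skipped <- skipped + 1L; next }
    a1 <- -log(w1); a2 <- -log(w2); bb <- -log(w3)
    k1 <- max((a1 - gY * bb) / (gR * bb), 0)
    k2 <- max((a2 - gR * bb) / (gY * bb), 0)
    k1s <- c(k1s, k1); k2s <- c(k2s, k2)
    Rs <- c(Rs, (gA * gG * k1 + gT * gC * k2) / (gR * gY))
    Ls <- c(Ls, L)
  }
  if (skipped > 0L) {
    warning(skipped, " saturated or transversion-free pair(s) skipped")
  }
  wmean <- function(x) if (length(x)) sum(x * Ls) / sum(Ls) else NA_real_
  structure(list(
    base_freqs = setNames(as.numeric(f), .BASES),
    k_purines = wmean(k1s), k_pyrimidines = wmean(k2s), R = wmean(Rs),
    sites_used = sites_used, pairs_used = length(Rs)
  ), class = "tstv_bias")
}

#' @export
print.tstv_bias <- function(x, ...) {
  cat(sprintf("Tamura-Nei bias: k1 = %.3f  k2 = %.3f  R = %.3f (%d sites, %d pairs)\n",
              x$k_purines, x$k_pyrimidines, x$R, x$sites_used, x$pairs_used))
  invisible(x)
}

#' Tamura-Nei pairwise distance matrix
#'
#' TN93 distances with pairwise deletion of gaps/ambiguities. Saturated
#' pairs (non-finite distance) are set to 1.5 times the largest finite
#' distance, with a warning.
#'
#' @param aligs a `gene_alignment`, character matrix, or list of
#'   `gene_alignment`s sharing species (columns are concatenated).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aligs) {
  if (is.list(aligs) && !inherits(aligs, "gene_alignment") &&
      !is.matrix(aligs)) {
    mats <- lapply(aligs, .as_alignment_matrix)
    common <- Reduce(intersect, lapply(mats, rownames))
    if (length(common) < 2L) stop("fewer than 2 shared species")
    mat <- do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
  } else {
    mat <- .as_alignment_matrix(aligs)
  }
  dna <- ape::as.DNAbin(tolower(mat))
  d <- as.matrix(ape::dist.dna(dna, model = "TN93", pairwise.deletion = TRUE))
  bad <- !is.finite(d)
  diag(bad) <- FALSE
  if (any(bad)) {
    warning(sum(bad) / 2, " saturated pair(s) set to 1.5 x max finite distance")
    d[bad] <- 1.5 * max(d[is.finite(d)])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param mat symmetric distance matrix with zero diagonal.
#' @return newick string (with the `phylo` tree attached as attribute
#'   `"phylo"`).
#' @export
nj_tree <- function(mat) {
  mat <- as.matrix(mat)
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-8)) ||
      any(abs(diag(mat)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  tr <- ape::nj(mat)
  nwk <- ape::write.tree(tr)
  attr(nwk, "phylo") <- tr
  nwk
}

#' Distance matrix reordered by tree tip order (heatmap export)
#'
#' @param mat distance matrix.
#' @param newick output of [nj_tree()] (or any newick string over the same
#'   labels).
#' @return the matrix with rows/columns in ladderized tip order.
#' @export
ordered_matrix <- function(mat, newick) {
  tr <- attr(newick, "phylo")
  if (is.null(tr)) tr <- ape::read.tree(text = as.character(newick))
  ord <- intersect(ape::ladderize(tr)$tip.label, rownames(mat))
  mat[ord, ord]
}

#' Bootstrap support for the NJ tree (resampling alignment columns)
#'
#' @param alig a `gene_alignment` or character matrix.
#' @param n_boot replicates.
#' @param seed integer seed for reproducibility.
#' @return list with `newick` and per-node `support` counts (out of
#'   `n_boot`).
#' @export
nj_bootstrap <- function(alig, n_boot = 100, seed = NULL) {
  mat <- .as_alignment_matrix(alig)
  if (!is.null(seed)) set.seed(seed)
  ref <- ape::nj(distance_matrix(mat))
  supp <- ape::boot.phylo(ref, mat, function(m) ape::nj(distance_matrix(m)),
                          B = n_boot, quiet = TRUE)
  nwk <- ape::write.tree(ref)
  attr(nwk, "phylo") <- ref
  list(newick = nwk, support = supp)
}
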