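# Codon-level mutation accounting under the vertebrate mitochondrial code
# (TGA = Trp, AGA/AGG = stop, ATA = Met), forward/backward amino-acid change
# matrices, and the CDS-vs-tRNA correlation battery (Pearson + partial
# Mantel).

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.mito_code <- function() {
  # NCBI translation table 2 (vertebrate mitochondrial)
  Biostrings::getGeneticCode("2")
}

#' Translate one codon under the vertebrate mitochondrial code
#'
#' @param codon 3-letter string over A,C,G,T.
#' @return 1-letter amino acid (or `"*"` for a stop).
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("codon contains a non-ACGT character: ", codon)
  }
  unname(.mito_code()[codon])
}

#' Classify a reference/alternate codon pair
#'
#' Complete codon pairs are compared by their translation: synonymous when
#' the amino acid is unchanged, truncation when the alternate codon is a
#' stop and the reference is not, nonsynonymous otherwise. A codon fully
#' gapped on either side is a (codon-length) deletion; a partially gapped
#' codon is a frameshift. A terminal `T--`/`TA-` reference or alternate
#' codon is treated as a polyadenylation-completed stop and flagged
#' `partial_stop`.
#'
#' @param ref_codon,alt_codon 3-character strings over A,C,G,T,-.
#' @param codon_index,gene bookkeeping fields copied into the result.
#' @param terminal is this the final codon of the CDS?
#' @return one-row data frame: `gene`, `codon_index`, `ref_codon`,
#'   `alt_codon`, `effect`, `ref_aa`, `alt_aa`, `partial_stop`.
#' @export
classify_codon_change <- function(ref_codon, alt_codon,
                                  codon_index = NA_integer_,
                                  gene = NA_character_, terminal = FALSE) {
  ref_codon <- toupper(ref_codon); alt_codon <- toupper(alt_codon)
  for (cd in c(ref_codon, alt_codon)) {
    if (!grepl("^[ACGT-]{3}$", cd)) {
      stop("codon contains an invalid character: ", cd)
    }
  }
  partial_stop <- FALSE
  complete_stop <- function(cd) {
    # T-- / TA- at the CDS end: completed to a stop by polyadenylation
    if (terminal && grepl("^T(A-|--)$", cd)) { partial_stop <<- TRUE; "TAA" }
    else cd
  }
  ref_codon2 <- complete_stop(ref_codon)
  alt_codon2 <- complete_stop(alt_codon)
  ngap_ref <- sum(.chars(ref_codon2) == "-")
  ngap_alt <- sum(.chars(alt_codon2) == "-")
  if (ngap_ref == 3L || ngap_alt == 3L) {
    effect <- "deletion"; ref_aa <- alt_aa <- NA_character_
  } else if (ngap_ref > 0L || ngap_alt > 0L) {
    effect <- "frameshift"; ref_aa <- alt_aa <- NA_character_
  } else {
    ref_aa <- translate_codon(ref_codon2)
    alt_aa <- translate_codon(alt_codon2)
    effect <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*" && ref_aa != "*") "truncation"
      else "nonsynonymous"
  }
  data.frame(gene = gene, codon_index = codon_index,
             ref_codon = ref_codon, alt_codon = alt_codon,
             effect = effect, ref_aa = ref_aa, alt_aa = alt_aa,
             partial_stop = partial_stop, stringsAsFactors = FALSE)
}

#' Classify every differing codon of an aligned CDS pair
#'
#' @param ref,alt equal-length codon-aligned sequences (length a multiple
#'   of 3; the reading frame is the reference frame).
#' @param gene gene name recorded in the output.
#' @return data frame of [classify_codon_change()] rows, one per codon at
#'   which the two sequences differ.
#' @export
classify_cds <- function(ref, alt, gene = NA_character_) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != nchar(alt)) stop("aligned sequences differ in length")
  if (nchar(ref) %% 3L != 0L) stop("aligned length is not a multiple of 3")
  n <- nchar(ref) %/% 3L
  out <- list()
  for (k in seq_len(n)) {
    i <- 3L * (k - 1L) + 1L
    rc <- substr(ref, i, i + 2L); ac <- substr(alt, i, i + 2L)
    if (rc == ac) next
    out[[length(out) + 1L]] <-
      classify_codon_change(rc, ac, codon_index = k, gene = gene,
                            terminal = k == n)
  }
  if (!length(out)) {
    return(classify_codon_change("AAA", "AAA")[0, ])
  }
  do.call(rbind, out)
}

#' Forward/backward amino-acid change matrix
#'
#' Each nonsynonymous change X -> Y increments the 20 x 20 matrix cell
#' (X, Y); the forward margin counts changes toward each amino acid
#' (column sums) and the backward margin changes away from it (row sums),
#' so both margins total the number of nonsynonymous substitutions.
#'
#' @param mutations data frame of codon-change rows (e.g. from
#'   [classify_cds()]); only `effect == "nonsynonymous"` rows with standard
#'   amino acids are tallied.
#' @return an `aa_change_matrix`: `matrix` (from = rows, to = columns),
#'   `forward`, `backward`, `total`.
#' @export
aa_change_matrix <- function(mutations) {
  m <- matrix(0L, 20L, 20L, dimnames = list(from = .AA, to = .AA))
  if (nrow(mutations)) {
    ns <- mutations[mutations$effect == "nonsynonymous" &
                      mutations$ref_aa %in% .AA &
                      mutations$alt_aa %in% .AA, , drop = FALSE]
    for (k in seq_len(nrow(ns))) {
      m[ns$ref_aa[k], ns$alt_aa[k]] <- m[ns$ref_aa[k], ns$alt_aa[k]] + 1L
    }
  }
  structure(list(matrix = m,
                 forward = colSums(m), backward = rowSums(m),
                 total = sum(m)),
            class = "aa_change_matrix")
}

#' @export
print.aa_change_matrix <- function(x, ...) {
  cat("aa_change_matrix:", x$total, "nonsynonymous changes\n")
  top <- sort(x$forward, decreasing = TRUE)[1:3]
  cat("  top forward:", paste(names(top), top, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Pearson correlation between two mutation-load vectors
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r` and two-tailed `p`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("vectors must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation battery with Benjamini-Hochberg correction
#'
#' @param xs,ys named lists of numeric vectors (all equal length); every
#'   pair (x, y) is tested.
#' @return data frame `x`, `y`, `r`, `p`, `p_bh`.
#' @export
correlation_battery <- function(xs, ys) {
  grid <- expand.grid(x = names(xs), y = names(ys),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    ct <- correlate(xs[[grid$x[k]]], ys[[grid$y[k]]])
    data.frame(x = grid$x[k], y = grid$y[k], r = ct$r, p = ct$p,
               stringsAsFactors = FALSE)
  }))
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res
}

.lower <- function(m) m[lower.tri(m)]

#' Partial Mantel test (residual permutation)
#'
#' Correlates the lower triangles of A and B after removing the linear
#' effect of C from each, and assesses significance by permuting the
#' rows/columns of A's residual matrix (one-tailed, greater). Seeded runs
#' are exactly reproducible.
#'
#' @param A,B,C symmetric matrices of the same dimension.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return list with `r_partial`, `p`, `n_perm`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 999, seed = NULL) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  n <- nrow(A)
  if (!all(dim(A) == n, dim(B) == n, dim(C) == n)) {
    stop("matrices must be square and of equal dimension")
  }
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  resid_mat <- function(X, Z) {
    fit <- stats::lm.fit(cbind(1, .lower(Z)), .lower(X))
    R <- X - (fit$coefficients[1] + fit$coefficients[2] * Z)
    diag(R) <- 0
    R
  }
  if (stats::sd(.lower(A)) == 0 || stats::sd(.lower(B)) == 0) {
    stop("zero variance in a distance matrix")
  }
  RA <- resid_mat(A, C)
  RB <- resid_mat(B, C)
  r_obs <- stats::cor(.lower(RA), .lower(RB))
  hits <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    r_k <- stats::cor(.lower(RA[p, p]), .lower(RB))
    if (r_k >= r_obs) hits <- hits + 1L
  }
  list(r_partial = r_obs, p = (hits + 1L) / (n_perm + 1L), n_perm = n_perm)
}
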