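# Domain-aware multiple alignment.
#
# Each tRNA gene is aligned across species per structural domain block:
# homologous domains (from the per-sequence cloverleaf annotations) are
# aligned independently with a center-star Needleman-Wunsch strategy and the
# blocks are concatenated, so gaps never cross a domain boundary. This
# mirrors manual structure-preserving alignment of ~70 nt tRNAs, for which
# per-block optimal pairwise alignment is exact and center-star is a
# well-behaved heuristic for k > 2.

# Block keys in canonical order. CC occurs in two blocks ("CC.1" = the
# connector after the acceptor stem, which also hosts the long D-replacement
# connector of D-armless genes; "CC.2" = the single position after the
# D-stem).
.BLOCK_KEYS <- c(
  "A-stem5'", "CC.1", "D-stem5'", "D-loop", "D-stem3'", "CC.2",
  "An-stem5'", "An-loop", "An-stem3'", "V-loop",
  "T-stem5'", "T-loop", "T-stem3'", "A-stem3'", "discriminator"
)

# Split an annotated sequence into named domain-block substrings.
.domain_blocks <- function(seq, ann) {
  bases <- .chars(toupper(seq))
  labs <- ann$domain_of
  r <- rle(labs)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  out <- setNames(rep("", length(.BLOCK_KEYS)), .BLOCK_KEYS)
  cc_seen <- 0L
  for (i in seq_along(r$values)) {
    lab <- r$values[i]
    key <- if (lab == "CC") {
      cc_seen <- cc_seen + 1L
      paste0("CC.", cc_seen)
    } else lab
    idx <- starts[i]:(starts[i] + r$lengths[i] - 1L)
    out[key] <- paste(bases[idx], collapse = "")
  }
  out
}

#' Pairwise global (Needleman-Wunsch) alignment
#'
#' @param a,b sequences (character strings; either may be empty).
#' @param match,mismatch,gap alignment scores.
#' @return list with gapped strings `a`, `b` and the optimal `score`.
#' @export
nw_align <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  x <- .chars(toupper(a)); y <- .chars(toupper(b))
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) {
    return(list(a = paste(c(x, rep("-", m)), collapse = ""),
                b = paste(c(rep("-", n), y), collapse = ""),
                score = gap * (n + m)))
  }
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(x[i] == y, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # traceback (ties: diagonal, then up/delete, then left/insert)
  i <- n; j <- m; ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] ==
          S[i, j] + (if (x[i] == y[j]) match else mismatch)) {
      ra <- c(x[i], ra); rb <- c(y[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(x[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(y[j], rb); j <- j - 1L
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = S[n + 1L, m + 1L])
}

# Center-star MSA of a character vector of strings; returns a character
# matrix (one row per input, gap = "-"), rows in input order.
.center_star <- function(strs, match = 2, mismatch = -1, gap = -2) {
  k <- length(strs)
  if (k == 1L) {
    return(matrix(.chars(strs), nrow = 1L))
  }
  if (length(unique(strs)) == 1L) {
    m <- matrix(rep(.chars(strs[1]), k), nrow = k, byrow = TRUE)
    if (nchar(strs[1]) == 0L) m <- matrix("", nrow = k, ncol = 0L)
    return(m)
  }
  # center = sequence maximizing summed pairwise score
  tot <- numeric(k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    s <- nw_align(strs[i], strs[j], match, mismatch, gap)$score
    tot[i] <- tot[i] + s; tot[j] <- tot[j] + s
  }
  ci <- which.max(tot)
  center <- .chars(strs[ci])
  master <- center                      # center with accumulated gaps
  rows <- list()                        # aligned rows, keyed by input index
  rows[[ci]] <- master
  for (i in setdiff(seq_len(k), ci)) {
    pw <- nw_align(strs[ci], strs[i], match, mismatch, gap)
    ac <- .chars(pw$a); as_ <- .chars(pw$b)
    if (length(as_) == 0L) ac <- as_ <- character(0)
    # merge pairwise alignment into the growing MSA via the center
    newmaster <- character(0); newrow <- character(0)
    keepcols <- list()                  # for old rows: source col or NA (gap)
    p <- 1L; q <- 1L
    nm <- length(master); na <- length(ac)
    while (p <= nm || q <= na) {
      if (p <= nm && master[p] == "-" && (q > na || ac[q] != "-")) {
        newmaster <- c(newmaster, "-"); newrow <- c(newrow, "-")
        keepcols <- c(keepcols, p); p <- p + 1L
      } else if (q <= na && ac[q] == "-") {
        newmaster <- c(newmaster, "-"); newrow <- c(newrow, as_[q])
        keepcols <- c(keepcols, NA); q <- q + 1L
      } else {
        newmaster <- c(newmaster, master[p]); newrow <- c(newrow, as_[q])
        keepcols <- c(keepcols, p); p <- p + 1L; q <- q + 1L
      }
    }
    keep <- unlist(keepcols)
    for (r in which(!vapply(rows, is.null, logical(1)))) {
      old <- rows[[r]]
      rows[[r]] <- ifelse(is.na(keep), "-", old[replace(keep, is.na(keep), 1L)])
    }
    rows[[i]] <- newrow
    master <- newmaster
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Align one tRNA gene across species, preserving structural domains
#'
#' @param seqs data frame of tRNA genes (columns `species_id`, `isotype`,
#'   `sequence`) or a named character vector of sequences (all one isotype).
#' @param anns list of `cloverleaf` annotations, parallel to `seqs`.
#' @param match,mismatch,gap alignment scores.
#' @return a `gene_alignment`: character matrix `matrix` (rows = species),
#'   per-column `column_domain` labels, `isotype`, `length`.
#' @export
align_gene <- function(seqs, anns, match = 2, mismatch = -1, gap = -2) {
  if (is.data.frame(seqs)) {
    species <- as.character(seqs$species_id)
    isotype <- unique(as.character(seqs$isotype))
    strings <- as.character(seqs$sequence)
  } else {
    species <- names(seqs)
    if (is.null(species)) species <- paste0("seq", seq_along(seqs))
    isotype <- NA_character_
    strings <- as.character(seqs)
  }
  if (length(isotype) > 1L) {
    stop("sequences of mixed isotype: ", paste(isotype, collapse = ", "))
  }
  if (length(strings) < 2L) stop("need at least 2 sequences to align")
  if (length(anns) != length(strings) || any(vapply(anns, is.null, logical(1)))) {
    stop("every sequence requires a cloverleaf annotation")
  }
  blocks <- t(vapply(seq_along(strings),
                     function(i) .domain_blocks(strings[i], anns[[i]]),
                     setNames(character(length(.BLOCK_KEYS)), .BLOCK_KEYS)))
  mats <- list(); doms <- character(0)
  for (key in .BLOCK_KEYS) {
    col <- blocks[, key]
    if (all(nchar(col) == 0L)) next
    m <- .center_star(col, match, mismatch, gap)
    if (ncol(m) == 0L) next
    mats[[key]] <- m
    doms <- c(doms, rep(sub("^CC\\.[12]$", "CC", key), ncol(m)))
  }
  mat <- do.call(cbind, mats)
  rownames(mat) <- species
  structure(list(isotype = isotype[1], matrix = mat,
                 column_domain = doms, length = ncol(mat)),
            class = "gene_alignment")
}

#' Construct a gene_alignment from pre-aligned rows
#'
#' @param rows named character vector of equal-length gapped sequences.
#' @param column_domain optional per-column domain labels.
#' @param isotype optional isotype tag.
#' @return a `gene_alignment`.
#' @export
gene_alignment <- function(rows, column_domain = NULL, isotype = NA_character_) {
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) stop("rows differ in length")
  mat <- do.call(rbind, lapply(rows, .chars))
  mat[] <- toupper(mat)
  rownames(mat) <- names(rows)
  if (!is.null(column_domain) && length(column_domain) != ncol(mat)) {
    stop("column_domain length differs from alignment length")
  }
  structure(list(isotype = isotype, matrix = mat,
                 column_domain = column_domain, length = ncol(mat)),
            class = "gene_alignment")
}

#' Gapped row strings of an alignment
#' @param alig a `gene_alignment`.
#' @export
alignment_strings <- function(alig) {
  apply(alig$matrix, 1L, paste, collapse = "")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("gene_alignment", if (!is.na(x$isotype)) x$isotype else "", ":",
      nrow(x$matrix), "sequences x", x$length, "columns\n")
  invisible(x)
}

#' Degenerate consensus of a gene alignment
#'
#' Per column: a base reaching `threshold` (as a fraction of non-gap
#' entries) is emitted directly; otherwise the minimal IUPAC degeneracy code
#' covering all bases tied for the maximal count is emitted. Columns in
#' which more than half the rows carry a gap are omitted (the consensus
#' serves as a substitution-calling reference; indels are scored
#' separately).
#'
#' @param alig a `gene_alignment`.
#' @param threshold fraction in `[0.5, 1]`; 0.95 reproduces the
#'   "bases match at least 95%" rule, 0.5 plain majority.
#' @return consensus string (possibly degenerate).
#' @export
consensus <- function(alig, threshold = 0.95) {
  if (threshold < 0.5 || threshold > 1) stop("threshold must be in [0.5, 1]")
  mat <- alig$matrix
  if (is.null(mat) || nrow(mat) == 0L || ncol(mat) == 0L) {
    stop("empty alignment")
  }
  out <- character(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (mean(col == "-") > 0.5) next
    bases <- col[col != "-"]
    cnt <- table(factor(bases, levels = .BASES))
    frac <- cnt / length(bases)
    if (max(frac) >= threshold) {
      out <- c(out, names(which.max(frac)))
    } else {
      tie <- names(cnt)[cnt == max(cnt)]
      out <- c(out, iupac_code(tie))
    }
  }
  paste(out, collapse = "")
}
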