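# Independent oracles used across the suite. Each re-derives its quantity
# through a different code path (or an external library) than the
# implementation it checks.

# --- column classification: direct case-by-case re-derivation -------------
oracle_classify <- function(col) {
  col <- toupper(col)
  n <- length(col)
  bases <- col[col != "-"]
  gaps <- n - length(bases)
  tab <- sort(table(bases), decreasing = TRUE)
  top <- max(tab)
  dominants <- sort(names(tab)[tab == top])
  rest <- tab[!names(tab) %in% dominants]
  best_sub <- if (length(rest)) max(rest) else 0L

  labels <- character(n)
  if (gaps > 0 && gaps > best_sub && gaps >= top) {
    # insertion column: the gap state dominates
    labels[col == "-"] <- "C"
    labels[col != "-"] <- "I"
    dominant <- "-"
  } else {
    cdes <- dominants[1]
    purine <- function(x) x %in% c("A", "G")
    for (i in seq_len(n)) {
      labels[i] <- if (col[i] == "-") "D"
        else if (col[i] == cdes) "C"
        else if (purine(col[i]) == purine(cdes)) "S"
        else "V"
    }
    dominant <- c(A = "A", C = "C", G = "G", T = "T",
                  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
                  CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
                  )[[paste(dominants, collapse = "")]]
  }
  list(dominant = dominant, labels = labels)
}

# --- Needleman-Wunsch optimal score via Biostrings ------------------------
oracle_nw_score <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  if (nchar(a) == 0L || nchar(b) == 0L) {
    return(gap * (nchar(a) + nchar(b)))
  }
  m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                mismatch = mismatch,
                                                baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = m, gapOpening = 0, gapExtension = -gap,
    type = "global"
  ))
}

# --- Tajima's D from the published definitions, with pi via ape -----------
oracle_tajima <- function(mat) {
  keep <- apply(mat, 2, function(cl) all(cl %in% c("A", "C", "G", "T")))
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  S <- sum(apply(mat, 2, function(cl) length(unique(cl))) > 1)
  if (S == 0) return(list(S = 0, D = NA_real_))
  dn <- ape::dist.dna(ape::as.DNAbin(tolower(mat)), model = "N")
  pi <- mean(dn)
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  V <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  list(S = S, pi = pi, D = (pi - S / a1) / sqrt(V))
}

# --- neutral infinite-sites coalescent simulation (for the D null) --------
sim_neutral_alignment <- function(n = 20, theta = 5) {
  tr <- ape::rcoal(n)
  nmut <- stats::rpois(nrow(tr$edge), theta / 2 * tr$edge.length)
  cols <- list()
  tipset <- function(node) {
    if (node <= n) return(node)
    unlist(lapply(tr$edge[tr$edge[, 1] == node, 2], tipset))
  }
  for (e in seq_len(nrow(tr$edge))) {
    if (nmut[e] == 0) next
    carriers <- tipset(tr$edge[e, 2])
    for (m in seq_len(nmut[e])) {
      col <- rep("A", n); col[carriers] <- "G"
      cols[[length(cols) + 1]] <- col
    }
  }
  if (!length(cols)) cols <- list(rep("A", n))
  mat <- do.call(cbind, cols)
  rownames(mat) <- tr$tip.label
  mat
}

# --- K80 pair/star simulation via closed-form transition probabilities ----
k80_evolve <- function(anc, d, kappa) {
  p_tv <- 0.5 - 0.5 * exp(-4 * d / (kappa + 2))
  p_ts <- 0.25 + 0.25 * exp(-4 * d / (kappa + 2)) -
    0.5 * exp(-2 * d * (kappa + 1) / (kappa + 2))
  TS <- c(A = "G", C = "T", G = "A", T = "C")
  TV <- list(A = c("C", "T"), C = c("A", "G"),
             G = c("C", "T"), T = c("A", "G"))
  u <- stats::runif(length(anc))
  out <- anc
  i <- u < p_ts
  out[i] <- TS[anc[i]]
  j <- u >= p_ts & u < p_ts + p_tv
  out[j] <- vapply(anc[j], function(x) sample(TV[[x]], 1), "")
  out
}

# --- GenBank flat-file writer for fixture records -------------------------
write_genbank_record <- function(path, accession, sequence, features,
                                 organism = "Synthetica testcase") {
  fmt_loc <- function(start, end, strand) {
    loc <- paste0(start, "..", end)
    if (strand == "reverse") paste0("complement(", loc, ")") else loc
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular VRT",
                     accession, nchar(sequence)), con)
  writeLines(sprintf("ACCESSION   %s", accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", nchar(sequence)), con)
  writeLines(sprintf('                     /organism="%s"', organism), con)
  for (k in seq_len(nrow(features))) {
    f <- features[k, ]
    writeLines(sprintf("     %-16s%s", f$type,
                       fmt_loc(f$start, f$end, f$strand)), con)
    if (!is.na(f$product)) {
      writeLines(sprintf('                     /product="%s"', f$product), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(sequence)
  for (i in seq(1, nchar(s), by = 60)) {
    chunk <- substr(s, i, min(i + 59, nchar(s)))
    blocks <- regmatches(chunk, gregexpr(".{1,10}", chunk))[[1]]
    writeLines(sprintf("%9d %s", i, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

# amino-acid 3-letter product names for the fixture writer
aa1_to_product <- function(iso) {
  map <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val")
  paste0("tRNA-", map[[substr(iso, 4, 4)]])
}
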