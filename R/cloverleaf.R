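# Cloverleaf domain annotation.
#
# A mitochondrial tRNA is partitioned into the structural domains used
# throughout the package: acceptor stem (A-stem), D arm (stem + loop),
# anticodon arm (An-stem + An-loop), variable loop (V-loop), T arm
# (T-stem + T-loop), the central connector positions (CC) and the unpaired
# discriminator base. Domains are laid out linearly as
#
#   A-stem5' | CC | D-stem5' | D-loop | D-stem3' | CC | An-stem5' | An-loop |
#   An-stem3' | V-loop | T-stem5' | T-loop | T-stem3' | A-stem3' | discriminator
#
# with the CC connector split across two short blocks (two nucleotides after
# the acceptor stem, matching standard tRNA numbering positions 8-9, and at
# most one nucleotide after the D-stem). D-armless genes (the mitochondrial
# trnS-GCU type) replace the whole D arm with a single CC connector.

.DOMAINS <- c(
  "A-stem5'", "CC", "D-stem5'", "D-loop", "D-stem3'",
  "An-stem5'", "An-loop", "An-stem3'", "V-loop",
  "T-stem5'", "T-loop", "T-stem3'", "A-stem3'", "discriminator"
)

# Structural constraints (template mode): fixed stems A=7, An=5, T=5;
# D-stem 3-4 bp; An-loop fixed at 7 nt; T-loop 7-9 nt; V-loop 4-6 nt;
# D-loop 3-10 nt. D-armless layouts (the trnS-GCU type) replace the D arm
# with a short connector and compensate with an enlarged variable arm, as
# in metazoan D-armless serine tRNAs.
.TPL <- list(
  a = 7L, an = 5L, t = 5L, anl = 7L, cc1 = 2L,
  d = 3:4, dl = 3:10, cc2 = 0:1, v = 4:6, tl = 7:9,
  cc_armless = 3:8, v_armless = 4:16
)

# Per-position domain labels for a given layout parameter list.
.layout_labels <- function(p) {
  if (isTRUE(p$armless)) {
    blocks <- c(
      "A-stem5'" = p$a, "CC" = p$cc, "An-stem5'" = p$an, "An-loop" = p$anl,
      "An-stem3'" = p$an, "V-loop" = p$v, "T-stem5'" = p$t, "T-loop" = p$tl,
      "T-stem3'" = p$t, "A-stem3'" = p$a, "discriminator" = 1L
    )
  } else {
    blocks <- c(
      "A-stem5'" = p$a, "CC" = p$cc1, "D-stem5'" = p$d, "D-loop" = p$dl,
      "D-stem3'" = p$d, "CC" = p$cc2, "An-stem5'" = p$an, "An-loop" = p$anl,
      "An-stem3'" = p$an, "V-loop" = p$v, "T-stem5'" = p$t, "T-loop" = p$tl,
      "T-stem3'" = p$t, "A-stem3'" = p$a, "discriminator" = 1L
    )
  }
  rep(names(blocks), times = blocks)
}

# Stem base-pair position table for a label vector.
.stem_pairs_from_labels <- function(labels) {
  out <- list()
  for (stem in c("A", "D", "An", "T")) {
    p5 <- which(labels == paste0(stem, "-stem5'"))
    p3 <- which(labels == paste0(stem, "-stem3'"))
    if (!length(p5)) next
    out[[stem]] <- data.frame(
      stem = stem, pos5 = p5, pos3 = rev(p3),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Layout score: complementary (Watson-Crick or G.T wobble) stem pairs
# minus non-complementary ones, so spuriously extending a stem over a
# non-pairing position never ties with the shorter stem.
.score_layout <- function(bases, labels) {
  pr <- .stem_pairs_from_labels(labels)
  if (is.null(pr) || !nrow(pr)) return(0L)
  a <- bases[pr$pos5]; b <- bases[pr$pos3]
  comp <- .is_wc(a, b) | .is_wobble(a, b)
  sum(comp) - sum(!comp)
}

.as_trna <- function(gene) {
  if (is.character(gene) && length(gene) == 1L) {
    return(list(sequence = gene, anticodon = NULL, gene_id = NA_character_))
  }
  list(
    sequence = as.character(gene$sequence[1]),
    anticodon = if (!is.null(gene$anticodon)) as.character(gene$anticodon[1]) else NULL,
    gene_id = if (!is.null(gene$gene_id)) as.character(gene$gene_id[1]) else NA_character_
  )
}

.new_cloverleaf <- function(gene_id, labels, bases, anticodon, armless) {
  stem_len <- function(s) sum(labels == paste0(s, "-stem5'"))
  loop_len <- function(l) sum(labels == l)
  structure(list(
    gene_id = gene_id,
    length = length(labels),
    domain_of = labels,
    stem_lengths = c(
      "A-stem" = stem_len("A"), "D-stem" = stem_len("D"),
      "An-stem" = stem_len("An"), "T-stem" = stem_len("T")
    ),
    loop_lengths = c(
      "D-loop" = loop_len("D-loop"), "An-loop" = loop_len("An-loop"),
      "V-loop" = loop_len("V-loop"), "T-loop" = loop_len("T-loop"),
      "CC" = loop_len("CC")
    ),
    d_armless = armless,
    anticodon = anticodon,
    pairs = .stem_pairs_from_labels(labels),
    bases = bases
  ), class = "cloverleaf")
}

#' Annotate the cloverleaf domains of a tRNA sequence
#'
#' Assigns every position of a tRNA gene to one structural domain, either
#' from a dot-bracket secondary structure or, when no structure is supplied,
#' by a template search under the canonical mitochondrial constraints
#' (A-stem 7 bp, An-stem 5 bp, T-stem 5 bp, D-stem 3-4 bp, An-loop 7 nt,
#' T-loop 7-9 nt, V-loop 4-6 nt, D-loop 3-10 nt). Template mode returns the
#' layout maximizing the number of complementary (Watson-Crick or G.T
#' wobble) stem pairs; D-armless layouts compete with D-armed ones so
#' trnS-GCU-type genes are detected automatically. Ties prefer an intact D
#' arm, then the longer D-stem, then the shorter D-loop.
#'
#' @param gene a character sequence, or a list/one-row data frame with
#'   `sequence` and optionally `anticodon` and `gene_id` fields.
#' @param structure optional dot-bracket string of the same length.
#' @return a `cloverleaf` object: per-position `domain_of` labels,
#'   `stem_lengths`, `loop_lengths`, `d_armless`, and the stem `pairs` table.
#' @export
annotate_domains <- function(gene, structure = NULL) {
  g <- .as_trna(gene)
  seq <- toupper(g$sequence)
  bases <- .chars(seq)
  L <- length(bases)
  if (!is.null(structure)) {
    return(.annotate_from_structure(g, bases, structure))
  }

  anticodon <- if (!is.null(g$anticodon)) toupper(g$anticodon) else NULL
  cands <- .enumerate_layouts(L)
  if (!length(cands)) {
    stop("unfoldable: no domain layout fits a sequence of length ", L)
  }
  if (!is.null(anticodon)) {
    ok <- vapply(cands, function(p) {
      s <- p$anl_start + 2L
      substr(seq, s, s + 2L) == anticodon
    }, logical(1))
    if (!any(ok)) {
      stop("anticodon not centered in any candidate An-loop for gene ",
           g$gene_id)
    }
    cands <- cands[ok]
  }
  scores <- vapply(cands, function(p) .score_layout(bases, p$labels), integer(1))
  best <- cands[[which.max(scores)]]  # candidates pre-sorted by tie-break order
  .new_cloverleaf(g$gene_id, best$labels, bases, anticodon, best$armless)
}

# Enumerate all layouts matching total length L, in deterministic
# tie-break order: D-armed before D-armless, longer D-stem first, shorter
# D-loop first, then smaller cc2, V-loop, T-loop.
.enumerate_layouts <- function(L) {
  out <- list()
  tpl <- .TPL
  for (d in rev(tpl$d)) for (dl in tpl$dl) for (cc2 in tpl$cc2)
    for (v in tpl$v) for (tl in tpl$tl) {
      if (44L + 2L * d + dl + cc2 + v + tl != L) next
      p <- list(a = tpl$a, cc1 = tpl$cc1, d = d, dl = dl, cc2 = cc2,
                an = tpl$an, anl = tpl$anl, v = v, t = tpl$t, tl = tl,
                armless = FALSE)
      p$labels <- .layout_labels(p)
      p$anl_start <- which(p$labels == "An-loop")[1]
      out[[length(out) + 1L]] <- p
    }
  for (cc in tpl$cc_armless) for (v in tpl$v_armless) for (tl in tpl$tl) {
    if (42L + cc + v + tl != L) next
    p <- list(a = tpl$a, cc = cc, an = tpl$an, anl = tpl$anl, v = v,
              t = tpl$t, tl = tl, armless = TRUE)
    p$labels <- .layout_labels(p)
    p$anl_start <- which(p$labels == "An-loop")[1]
    out[[length(out) + 1L]] <- p
  }
  out
}

# Structure mode: derive domains from a balanced dot-bracket string.
.annotate_from_structure <- function(g, bases, structure) {
  L <- length(bases)
  pairs <- parse_dotbracket(structure)
  if (nchar(structure) != L) {
    stop("structure length differs from sequence length for gene ", g$gene_id)
  }
  # group pairs into stacked helices
  pairs <- pairs[order(pairs$open), , drop = FALSE]
  if (!nrow(pairs)) stop("unfoldable: no base pairs in structure")
  helix_id <- cumsum(c(1L, diff(pairs$open) != 1L |
                             diff(pairs$close) != -1L))
  helices <- split(pairs, helix_id)
  h5 <- vapply(helices, function(h) min(h$open), integer(1))
  helices <- helices[order(h5)]
  acc <- helices[[1]]
  inner <- helices[-1]
  if (length(inner) < 2L || length(inner) > 3L) {
    stop("unfoldable: expected 2 or 3 inner helices (got ", length(inner), ")")
  }
  armless <- length(inner) == 2L
  labels <- rep(NA_character_, L)
  put <- function(idx, lab) labels[idx] <<- lab
  put(acc$open, "A-stem5'"); put(acc$close, "A-stem3'")
  names(inner) <- if (armless) c("An", "T") else c("D", "An", "T")
  for (nm in names(inner)) {
    h <- inner[[nm]]
    put(h$open, paste0(nm, "-stem5'"))
    put(h$close, paste0(nm, "-stem3'"))
    loop <- (max(h$open) + 1L):(min(h$close) - 1L)
    put(loop, paste0(nm, if (nm == "An") "-loop" else "-loop"))
  }
  # unpaired regions outside hairpin loops
  an5 <- min(inner[["An"]]$open)
  t5 <- min(inner[["T"]]$open)
  un <- which(is.na(labels))
  for (i in un) {
    labels[i] <- if (i < an5) "CC"
      else if (i < t5) "V-loop"
      else "discriminator"
  }
  disc <- which(labels == "discriminator")
  if (length(disc) > 1L) {
    tail_seq <- paste(bases[disc[-1]], collapse = "")
    if (identical(tail_seq, "CCA")) {
      warning("trailing unpaired CCA after the discriminator; labeled CC ",
              "(mitochondrial tRNA genes do not encode CCA)")
      labels[disc[-1]] <- "CC"
    } else {
      labels[disc[-1]] <- "V-loop"  # absorb unexpected unpaired tail
    }
  }
  anl <- which(labels == "An-loop")
  if (length(anl) < 3L) stop("anticodon loop shorter than 3 nt")
  if (!is.null(g$anticodon)) {
    ac <- paste(bases[anl[3:5]], collapse = "")
    if (length(anl) < 5L || ac != toupper(g$anticodon)) {
      warning("anticodon not centered in the anticodon loop for gene ",
              g$gene_id)
    }
  }
  .new_cloverleaf(g$gene_id, labels, bases, g$anticodon, armless)
}

#' Parse a dot-bracket string into a base-pair table
#'
#' @param structure dot-bracket string using `(`, `)` and `.`.
#' @return data frame with columns `open` and `close` (1-based positions).
#' @export
parse_dotbracket <- function(structure) {
  ch <- .chars(structure)
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad)) stop("invalid dot-bracket character(s): ",
                        paste(bad, collapse = " "))
  stack <- integer(0)
  open <- integer(0); close <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      open <- c(open, stack[length(stack)])
      close <- c(close, i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '(' at ",
                          stack[length(stack)])
  data.frame(open = open, close = close)[order(open), , drop = FALSE]
}

#' Report non-canonical stem pairs
#'
#' Scans all stem base pairs of an annotated tRNA and returns those that are
#' not Watson-Crick. G.T pairs are reported with `wobble = TRUE` so both the
#' strict convention (wobble = valid pair) and the loose one (wobble =
#' mismatch) are recoverable from the same table.
#'
#' @param gene tRNA gene (sequence string or list with `sequence`).
#' @param ann `cloverleaf` annotation from [annotate_domains()].
#' @return data frame: `stem`, `pos5`, `pos3`, `base5`, `base3`, `wobble`.
#' @export
pairing_mismatches <- function(gene, ann) {
  g <- .as_trna(gene)
  bases <- .chars(toupper(g$sequence))
  pr <- ann$pairs
  if (is.null(pr) || !nrow(pr)) {
    stop("annotation has no stem pairs")
  }
  a <- bases[pr$pos5]; b <- bases[pr$pos3]
  keep <- !.is_wc(a, b)
  out <- data.frame(
    stem = pr$stem[keep], pos5 = pr$pos5[keep], pos3 = pr$pos3[keep],
    base5 = a[keep], base3 = b[keep],
    wobble = .is_wobble(a[keep], b[keep]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-position domain table
#'
#' @param ann a `cloverleaf` annotation.
#' @return data frame `gene_id`, `position`, `base`, `domain` suitable for
#'   CSV export.
#' @export
domain_table <- function(ann) {
  data.frame(
    gene_id = ann$gene_id,
    position = seq_len(ann$length),
    base = ann$bases,
    domain = ann$domain_of,
    stringsAsFactors = FALSE
  )
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat("cloverleaf annotation", if (!is.na(x$gene_id)) x$gene_id else "", "\n")
  cat("  length:", x$length, "nt;",
      if (x$d_armless) "D-armless" else "four-armed", "\n")
  cat("  stems (bp):",
      paste(names(x$stem_lengths), x$stem_lengths, collapse = ", "), "\n")
  cat("  loops (nt):",
      paste(names(x$loop_lengths), x$loop_lengths, collapse = ", "), "\n")
  invisible(x)
}
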