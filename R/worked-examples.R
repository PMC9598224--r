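# Worked-example fixtures: three-species trnC and trnD alignments for the
# Nile haplotilapiine trio (O. niloticus, S. galilaeus, C. zillii),
# reconstructed from their printed constraints. Only the polymorphic
# positions, substitution types, carrier species, stem lengths and the two
# noncanonical stem pairs are fixed by those constraints; the remaining
# background bases are generated deterministically from a fixed internal
# seed and are otherwise arbitrary.

.EGYPT_SPECIES <- c("O_niloticus", "S_galilaeus", "C_zillii")

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# backbone: random loops, complementary stems, anticodon centered, then
# positional overrides
.example_backbone <- function(layout, anticodon, overrides) {
  labels <- .layout_labels(layout)
  bases <- sample(.BASES, length(labels), replace = TRUE)
  pairs <- .stem_pairs_from_labels(labels)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  anl <- which(labels == "An-loop")
  bases[anl[3:5]] <- .chars(anticodon)
  for (p in names(overrides)) bases[as.integer(p)] <- overrides[[p]]
  # complement 3' stem strands from the 5' strands, then re-apply overrides
  bases[pairs$pos3] <- comp[bases[pairs$pos5]]
  for (p in names(overrides)) bases[as.integer(p)] <- overrides[[p]]
  list(bases = bases, labels = labels)
}

#' Reconstructed three-species worked-example alignments
#'
#' `trnC_egypt`: a 66-column trnC alignment (D-stem 4 bp, D-loop 3 nt)
#' polymorphic only at positions 16, 19, 20, 25, 27, 47 and 62, every
#' substitution a transition, four minority alleles carried by the third
#' sequence (C. zillii), and the noncanonical stem pairs T5.G61 (acceptor
#' stem) and G10.T20 (D-stem) present in the shared backbone.
#'
#' `trnD_egypt`: a 73-column trnD alignment identical across species in
#' length, variable only at positions 15, 17, 20, 21, 56, 57, 59, 64 and
#' 73; position 17 carries three variants; the two-variant substitutions
#' are G/A at 15, 57 and 64, T/C at 20, C/T at 21, A/T at 56 (the single
#' transversion) and A/G at 59 and 73; the C50.A64 T-stem mispair is
#' private to C. zillii.
#'
#' @param name `"trnC_egypt"` or `"trnD_egypt"`.
#' @return list with `alignment` (a `gene_alignment`) and `annotation`
#'   (the backbone `cloverleaf`).
#' @export
worked_example <- function(name = c("trnC_egypt", "trnD_egypt")) {
  name <- match.arg(name)
  if (name == "trnC_egypt") {
    layout <- list(armless = FALSE, a = 7L, cc1 = 2L, d = 4L, dl = 3L,
                   cc2 = 0L, an = 5L, anl = 7L, v = 4L, t = 5L, tl = 7L)
    bk <- .with_seed(661016L, .example_backbone(
      layout, anticodon = "GCA",
      overrides = list(`5` = "T", `61` = "G",    # T5.G61 wobble (A-stem)
                       `10` = "G", `20` = "T")   # G10.T20 wobble (D-stem)
    ))
    # all seven substitutions are transitions; C. zillii carries four
    carriers <- list(O_niloticus = c(19L, 47L), S_galilaeus = 25L,
                     C_zillii = c(16L, 20L, 27L, 62L))
    anticodon <- "GCA"
  } else {
    layout <- list(armless = FALSE, a = 7L, cc1 = 2L, d = 4L, dl = 8L,
                   cc2 = 1L, an = 5L, anl = 7L, v = 5L, t = 5L, tl = 7L)
    bk <- .with_seed(731016L, .example_backbone(
      layout, anticodon = "GTC",
      overrides = list(`15` = "G", `17` = "G", `20` = "T", `21` = "C",
                       `56` = "A", `57` = "G", `59` = "A",
                       `50` = "C",              # pairs G64; zillii A64 mispairs
                       `73` = "A")
    ))
    carriers <- list(O_niloticus = c(20L, 59L), S_galilaeus = c(15L, 21L, 56L),
                     C_zillii = c(57L, 64L, 73L))
    anticodon <- "GTC"
  }
  rows <- matrix(rep(bk$bases, 3L), nrow = 3L, byrow = TRUE,
                 dimnames = list(.EGYPT_SPECIES, NULL))
  variant <- function(base, pos) {
    if (name == "trnD_egypt" && pos == 56L) return("T")   # A -> T transversion
    .TRANSITION[[base]]
  }
  for (sp in names(carriers)) {
    for (pos in carriers[[sp]]) {
      rows[sp, pos] <- variant(rows[sp, pos], pos)
    }
  }
  if (name == "trnD_egypt") {
    # three-variant site 17: G (niloticus) / A (galilaeus) / T (zillii)
    rows["S_galilaeus", 17L] <- "A"
    rows["C_zillii", 17L] <- "T"
  }
  alig <- structure(list(
    isotype = if (name == "trnC_egypt") "trnC" else "trnD",
    matrix = rows, column_domain = bk$labels, length = ncol(rows)
  ), class = "gene_alignment")
  ann <- .new_cloverleaf(
    gene_id = paste0(alig$isotype, "_consensus"),
    labels = bk$labels, bases = bk$bases, anticodon = anticodon,
    armless = FALSE
  )
  list(alignment = alig, annotation = ann)
}
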