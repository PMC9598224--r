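# Shared nucleotide helpers: IUPAC degeneracy codes, complements,
# transition/transversion classification.

.BASES <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

# base-set -> minimal IUPAC code (keys are sorted, comma-joined base sets)
.IUPAC_OF_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "A,G" = "R", "C,T" = "Y", "C,G" = "S", "A,T" = "W",
  "G,T" = "K", "A,C" = "M",
  "C,G,T" = "B", "A,G,T" = "D", "A,C,T" = "H", "A,C,G" = "V",
  "A,C,G,T" = "N"
)

#' Minimal IUPAC degeneracy code covering a set of bases
#'
#' @param bases character vector of unambiguous bases (subset of A, C, G, T).
#' @return single IUPAC character.
#' @keywords internal
iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = ",")
  code <- .IUPAC_OF_SET[key]
  if (is.na(code)) stop("not a set of unambiguous bases: ", key)
  unname(code)
}

#' Expand an IUPAC code into its member bases
#' @keywords internal
iupac_expand <- function(code) {
  code <- toupper(code)
  hit <- names(.IUPAC_OF_SET)[.IUPAC_OF_SET == code]
  if (length(hit) != 1L) stop("unknown IUPAC code: ", code)
  strsplit(hit, ",", fixed = TRUE)[[1]]
}

#' Reverse complement of a DNA string (IUPAC-aware)
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Is a base substitution a transition?
#'
#' Transitions stay within a nitrogenous-base class (purine to purine or
#' pyrimidine to pyrimidine); transversions cross classes.
#' @keywords internal
is_transition <- function(a, b) {
  (a %in% .PURINES & b %in% .PURINES) |
    (a %in% .PYRIMIDINES & b %in% .PYRIMIDINES)
}

# split a sequence string into a character vector of single bases
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# fraction of ambiguous (non-ACGT, non-gap) characters
.frac_ambiguous <- function(seq) {
  ch <- .chars(toupper(seq))
  ch <- ch[ch != "-"]
  if (!length(ch)) return(0)
  mean(!ch %in% .BASES)
}

# Watson-Crick pair?
.is_wc <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG")
}

# G-U wobble (G.T at DNA level)?
.is_wobble <- function(a, b) {
  paste0(a, b) %in% c("GT", "TG")
}
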