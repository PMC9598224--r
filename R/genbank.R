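# Minimal GenBank flat-file reader (LOCUS/ACCESSION, FEATURES, ORIGIN) and
# tRNA gene extraction with strand normalization. Only the feature types and
# location forms that occur in mitogenome records are handled
# (`start..end`, `complement(start..end)`); joined locations are skipped
# with a warning.

.AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

#' Read GenBank flat-file records
#'
#' @param path path to a GenBank flat file (one or more records separated by
#'   `//`).
#' @return list of records, each a list with `accession`, `organism`,
#'   `sequence` and a `features` data frame (`type`, `start`, `end`,
#'   `strand`, plus `product`, `gene` and `note` qualifiers).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(0, utils::head(lines, -1) == "//")))
  out <- lapply(recs, .parse_genbank_record)
  out[!vapply(out, is.null, logical(1))]
}

.parse_genbank_record <- function(lines) {
  lines <- lines[lines != "//"]
  if (!any(grepl("^LOCUS", lines))) return(NULL)
  acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
             grep("^ACCESSION", lines, value = TRUE)[1])
  if (is.na(acc)) {
    acc <- sub("^LOCUS\\s+(\\S+).*$", "\\1",
               grep("^LOCUS", lines, value = TRUE)[1])
  }
  org <- grep("^\\s+/organism=", lines, value = TRUE)[1]
  organism <- if (!is.na(org)) gsub('.*="([^"]*)".*', "\\1", org) else NA_character_

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(ostart)) {
    body <- lines[(ostart[1] + 1L):length(lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  features <- data.frame(type = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         product = character(0), gene = character(0),
                         note = character(0), stringsAsFactors = FALSE)
  if (length(fstart)) {
    fend <- if (length(ostart)) ostart[1] - 1L else length(lines)
    flines <- lines[(fstart[1] + 1L):fend]
    # a feature starts at indentation 5 with a type token
    starts <- grep("^ {5}\\S", flines)
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1L] - 1L else length(flines)
      blk <- flines[from:to]
      head1 <- blk[1]
      type <- sub("^ {5}(\\S+).*$", "\\1", head1)
      loc <- trimws(sub("^ {5}\\S+\\s+", "", head1))
      if (grepl("join", loc)) {
        warning("joined location skipped for feature ", type)
        next
      }
      strand <- if (grepl("^complement", loc)) "reverse" else "forward"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) < 2L) next
      qual <- function(name) {
        ln <- grep(paste0("^\\s+/", name, "="), blk, value = TRUE)[1]
        if (is.na(ln)) NA_character_ else gsub('.*="?([^"]*)"?.*', "\\1", ln)
      }
      features <- rbind(features, data.frame(
        type = type, start = as.integer(nums[1]), end = as.integer(nums[2]),
        strand = strand, product = qual("product"), gene = qual("gene"),
        note = qual("note"), stringsAsFactors = FALSE
      ))
    }
  }
  list(accession = acc, organism = organism, sequence = seq,
       features = features)
}

# resolve "tRNA-Phe" / "trnF" style labels to an amino-acid letter
.trna_aa_letter <- function(product, gene) {
  if (!is.na(product) && grepl("^tRNA-", product)) {
    aa3 <- sub("^tRNA-([A-Za-z]{3}).*$", "\\1", product)
    return(unname(.AA3_TO_1[aa3]))
  }
  if (!is.na(gene) && grepl("^trn", gene, ignore.case = TRUE)) {
    return(toupper(substr(gene, 4L, 4L)))
  }
  NA_character_
}

#' Extract tRNA genes from a GenBank record
#'
#' Reverse-strand features are reverse-complemented so every returned
#' sequence is the 5'->3' gene product. The two leucine and two serine
#' genes are disambiguated by the anticodon read from the template-mode
#' cloverleaf annotation of each gene.
#'
#' @param record one record from [read_genbank()].
#' @return TRNAGene data frame (`gene_id`, `species_id`, `isotype`,
#'   `anticodon`, `strand`, `start`, `end`, `sequence`), with attribute
#'   `incomplete = TRUE` when fewer than 20 distinct isotypes were
#'   resolved.
#' @export
extract_trna_genes <- function(record) {
  fx <- record$features
  fx <- fx[fx$type == "tRNA", , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(fx))) {
    aa <- .trna_aa_letter(fx$product[k], fx$gene[k])
    if (is.na(aa) || !aa %in% .AA3_TO_1) {
      warning("skipping tRNA feature with unresolvable isotype (",
              fx$product[k], ")")
      next
    }
    seq <- substr(record$sequence, fx$start[k], fx$end[k])
    if (fx$strand[k] == "reverse") seq <- revcomp(seq)
    isotype <- paste0("trn", aa)
    known <- .MT_TRNAS[substr(.MT_TRNAS$isotype, 4L, 4L) == aa, ]
    # anticodon read from the best-scoring annotation among the isotype's
    # known anticodons (disambiguates the L/L and S/S duplicates)
    cand <- lapply(known$anticodon, function(ac) {
      tryCatch(annotate_domains(list(sequence = seq, anticodon = ac)),
               error = function(e) NULL)
    })
    ok <- !vapply(cand, is.null, logical(1))
    if (!any(ok)) {
      warning("skipping ", isotype, " feature: no known anticodon fits ",
              "a cloverleaf layout")
      next
    }
    scores <- vapply(which(ok), function(i) {
      .score_layout(.chars(toupper(seq)), cand[[i]]$domain_of)
    }, numeric(1))
    best <- which(ok)[which.max(scores)]
    anticodon <- known$anticodon[best]
    isotype <- known$isotype[best]
    out[[length(out) + 1L]] <- data.frame(
      gene_id = paste(record$accession, isotype, sep = "_"),
      species_id = record$accession, isotype = isotype,
      anticodon = anticodon, strand = fx$strand[k],
      start = fx$start[k], end = fx$end[k], sequence = seq,
      stringsAsFactors = FALSE
    )
  }
  genes <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), species_id = character(0),
               isotype = character(0), anticodon = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               sequence = character(0), stringsAsFactors = FALSE)
  if (length(unique(genes$isotype)) < 20L) {
    attr(genes, "incomplete") <- TRUE
    warning("record ", record$accession, " resolved fewer than 20 tRNA ",
            "isotypes; flagged incomplete")
  }
  genes
}
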