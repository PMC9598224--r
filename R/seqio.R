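# Sequence and table IO: FASTA (via Biostrings), dot-bracket structure
# files, cohort membership tables, and deterministic QC filters for
# assembled gene sets.

#' Read a (possibly gapped) FASTA file
#'
#' @param path file path.
#' @return named uppercase character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path file path.
#' @param width line-wrapping width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Write an alignment (or its consensus) to FASTA
#'
#' @param alig a `gene_alignment`.
#' @param path file path.
#' @export
write_alignment_fasta <- function(alig, path) {
  write_fasta(alignment_strings(alig), path)
}

#' Read a tab-separated structure file (id, dot-bracket)
#'
#' Each line pairs a gene identifier with a balanced dot-bracket string;
#' unbalanced brackets are a hard error naming the offending line.
#'
#' @param path file path.
#' @return named character vector of dot-bracket strings.
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- character(0)
  for (k in seq_along(lines)) {
    parts <- strsplit(trimws(lines[k]), "[\t ]+")[[1]]
    if (length(parts) != 2L) {
      stop("structure file line ", k, ": expected 'id<TAB>structure'")
    }
    ok <- tryCatch({ parse_dotbracket(parts[2]); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) {
      stop("structure file line ", k, " (", parts[1], "): ",
           conditionMessage(ok))
    }
    out[parts[1]] <- parts[2]
  }
  out
}

#' Check structures against their gene sequences
#'
#' @param structures named dot-bracket vector (from
#'   [read_structure_file()]).
#' @param genes TRNAGene data frame with `gene_id` and `sequence`.
#' @return invisibly `TRUE`; errors name the mismatching gene.
#' @export
validate_structures <- function(structures, genes) {
  for (gid in names(structures)) {
    i <- match(gid, genes$gene_id)
    if (is.na(i)) next
    if (nchar(structures[[gid]]) != nchar(genes$sequence[i])) {
      stop("structure length differs from sequence length for gene ", gid)
    }
  }
  invisible(TRUE)
}

#' Read a cohort membership table
#'
#' CSV with header `species_id,in_family,in_sublineage`. The sublineage
#' (Ht) must be a subset of the family cohort (Ci) and species must be
#' unique.
#'
#' @param path file path.
#' @return data frame with logical membership columns.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "in_family", "in_sublineage")
  if (!all(need %in% names(df))) {
    stop("cohort table must have columns ", paste(need, collapse = ", "))
  }
  df$in_family <- as.logical(df$in_family)
  df$in_sublineage <- as.logical(df$in_sublineage)
  if (anyDuplicated(df$species_id)) stop("duplicated species_id in cohort table")
  if (any(df$in_sublineage & !df$in_family)) {
    stop("sublineage (Ht) must be a subset of the family cohort (Ci)")
  }
  df
}

#' Deterministic QC filter for an assembled tRNA gene set
#'
#' Stands in for manual curation of public mitogenomes: a species is dropped
#' when it misses any of the 22 tRNA isotypes, when any of its genes is a
#' per-isotype length outlier (outside mean +/- `sd_mult` SD across
#' species), or when any gene carries more than `max_ambiguous` ambiguous
#' bases.
#'
#' @param genes TRNAGene data frame.
#' @param sd_mult length-outlier threshold in SD units.
#' @param max_ambiguous maximal tolerated fraction of non-ACGT bases.
#' @return list with `kept` (filtered data frame) and `removed` (data frame
#'   `species_id`, `reason`).
#' @export
qc_filter_genes <- function(genes, sd_mult = 3, max_ambiguous = 0.05) {
  removed <- list()
  drop <- function(sp, why) {
    removed[[length(removed) + 1L]] <<- data.frame(
      species_id = sp, reason = why, stringsAsFactors = FALSE
    )
  }
  for (sp in unique(genes$species_id)) {
    isos <- genes$isotype[genes$species_id == sp]
    missing <- setdiff(.MT_TRNAS$isotype, isos)
    if (length(missing)) {
      drop(sp, paste("missing isotype(s):", paste(missing, collapse = " ")))
    }
  }
  for (iso in unique(genes$isotype)) {
    sub <- genes[genes$isotype == iso, ]
    len <- nchar(sub$sequence)
    if (length(len) >= 3L && stats::sd(len) > 0) {
      out <- abs(len - mean(len)) > sd_mult * stats::sd(len)
      for (sp in sub$species_id[out]) {
        drop(sp, paste0("length outlier in ", iso))
      }
    }
  }
  amb <- vapply(genes$sequence, .frac_ambiguous, numeric(1))
  for (k in which(amb > max_ambiguous)) {
    drop(genes$species_id[k],
         paste0("ambiguous bases > ", max_ambiguous * 100, "% in ",
                genes$isotype[k]))
  }
  removed <- if (length(removed)) unique(do.call(rbind, removed)) else
    data.frame(species_id = character(0), reason = character(0))
  list(kept = genes[!genes$species_id %in% removed$species_id, ],
       removed = removed)
}

#' Write the standard outputs of a synthetic cohort
#'
#' @param cohort a `trna_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  for (iso in names(cohort$alignments)) {
    al <- cohort$alignments[[iso]]
    write_alignment_fasta(al, file.path(dir, paste0(iso, ".aln.fasta")))
    ungapped <- gsub("-", "", alignment_strings(al), fixed = TRUE)
    write_fasta(ungapped, file.path(dir, paste0(iso, ".fasta")))
  }
  for (cg in names(cohort$cds)) {
    write_fasta(apply(cohort$cds[[cg]], 1L, paste, collapse = ""),
                file.path(dir, paste0(cg, ".cds.fasta")))
  }
  write_fasta(cohort$genomes, file.path(dir, "genomes.fasta"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Per-column classification table for CSV export
#'
#' @param classified output of [classify_alignment()].
#' @return long data frame `column`, `domain`, `dominant`, `species`,
#'   `label`.
#' @export
classification_table <- function(classified) {
  do.call(rbind, lapply(seq_along(classified$classifications), function(k) {
    cl <- classified$classifications[[k]]
    data.frame(
      column = cl$column_index,
      domain = if (!is.null(classified$column_domain)) {
        classified$column_domain[k]
      } else NA_character_,
      dominant = cl$dominant,
      species = names(cl$labels),
      label = unname(cl$labels),
      stringsAsFactors = FALSE
    )
  }))
}
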