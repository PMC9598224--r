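# Substitution quantification.
#
# Every alignment column is treated as a locus and every sequence at that
# column is labeled against the dominant (most frequent) base:
#   C  conserved (carries the dominant base),
#   S  transition from the dominant base (within purines or pyrimidines),
#   V  transversion from the dominant base (across the classes),
#   D  deletion (gap, when gaps are rarer than the commonest substitution),
#   I  insertion (base carried by a minority when the gap state dominates).
# Ties among equally frequent bases make the dominant base degenerate
# (minimal IUPAC code); one member of the tie set -- the earliest in
# A < C < G < T order -- is the conserved designate and the other members are
# scored as substitutions relative to it.
#
# Category totals are then converted to weights on the fixed grid
# 0.00/0.25/0.50/0.75/1.00 (rarest category gets the largest weight), summed
# per tRNA, per domain and per species, and cohort-contrasted by z-scores.

.CATEGORIES <- c("C", "S", "V", "D", "I")
# tie-break order for equal category totals in the ranked weighting
.WEIGHT_TIE_ORDER <- c("C", "V", "S", "D", "I")
.WEIGHT_GRID <- c(0.00, 0.25, 0.50, 0.75, 1.00)

#' Classify one alignment column against its dominant base
#'
#' @param column character vector of symbols in `A,C,G,T,-`, optionally
#'   named by species.
#' @param column_index optional 1-based index recorded in the result.
#' @return a `column_classification`: `dominant` (IUPAC base or `-`),
#'   per-species `labels`, and `counts` over the five categories.
#' @export
classify_column <- function(column, column_index = NA_integer_) {
  col <- toupper(as.character(column))
  if (length(col) < 2L) stop("a column needs at least 2 entries")
  bad <- setdiff(unique(col), c(.BASES, "-"))
  if (length(bad)) stop("invalid symbols in column: ", paste(bad, collapse = " "))
  if (all(col == "-")) stop("vacuous column: all entries are gaps")
  species <- names(column)
  if (is.null(species)) species <- paste0("s", seq_along(col))

  cnt <- table(factor(col[col != "-"], levels = .BASES))
  m <- max(cnt)
  tie <- names(cnt)[cnt == m]                    # co-dominant base set
  sub_max <- if (length(cnt[!names(cnt) %in% tie])) {
    max(cnt[!names(cnt) %in% tie])
  } else 0L
  g <- sum(col == "-")

  labels <- character(length(col))
  if (g > sub_max && g >= m) {
    # gap state dominates: bases present are insertions
    dominant <- "-"
    labels[col == "-"] <- "C"
    labels[col != "-"] <- "I"
  } else {
    dominant <- iupac_code(tie)
    cdes <- sort(tie)[1]                         # conserved designate
    labels[col == "-"] <- "D"
    base_idx <- which(col != "-")
    b <- col[base_idx]
    labels[base_idx] <- ifelse(
      b == cdes, "C", ifelse(is_transition(b, cdes), "S", "V")
    )
  }
  counts <- table(factor(labels, levels = .CATEGORIES))
  structure(list(
    column_index = column_index,
    dominant = dominant,
    labels = setNames(labels, species),
    counts = setNames(as.integer(counts), .CATEGORIES)
  ), class = "column_classification")
}

#' Classify every column of a gene alignment
#'
#' All-gap columns (which can arise when an alignment is subset to a cohort)
#' are dropped, together with their domain labels.
#'
#' @param alig a `gene_alignment`.
#' @return list with `classifications` (one per retained column),
#'   `column_domain`, and `totals` (summed category counts).
#' @export
classify_alignment <- function(alig) {
  mat <- alig$matrix
  keep <- which(colSums(mat != "-") > 0L)
  cls <- lapply(keep, function(j) classify_column(mat[, j], column_index = j))
  totals <- Reduce(`+`, lapply(cls, `[[`, "counts"))
  list(
    classifications = cls,
    column_domain = if (!is.null(alig$column_domain)) {
      alig$column_domain[keep]
    } else NULL,
    totals = totals
  )
}

#' Count-ranked categorical weights
#'
#' Categories sorted by descending total count receive the fixed weights
#' 0.00, 0.25, 0.50, 0.75, 1.00 in order, so the commonest category gets
#' 0.00 and the rarest the largest weight. Ties are broken by the fixed
#' order C, V, S, D, I. When only substitutions occur
#' (`substitution_only = TRUE`), fixed weights are used instead: 0.25 per
#' transition and 0.50 per transversion (conserved 0.00).
#'
#' @param totals named count vector over categories (subset of C,S,V,D,I).
#' @param substitution_only logical.
#' @return named numeric weight vector (class `category_weights`).
#' @export
assign_weights <- function(totals, substitution_only = FALSE) {
  if (!length(totals)) stop("totals must be non-empty")
  if (substitution_only) {
    w <- c(C = 0.00, S = 0.25, V = 0.50)
    return(structure(w, class = "category_weights"))
  }
  cats <- names(totals)
  if (length(cats) > 5L) stop("more than 5 categories")
  unknown <- setdiff(cats, .CATEGORIES)
  if (length(unknown)) stop("unknown categories: ", paste(unknown, collapse = " "))
  ord <- order(-as.numeric(totals), match(cats, .WEIGHT_TIE_ORDER))
  w <- setNames(.WEIGHT_GRID[seq_along(cats)], cats[ord])
  structure(w[cats], class = "category_weights")  # back to input order
}

#' Weighted variability profile of one gene alignment
#'
#' Sums the per-position weights over all sequences: separately for SNP
#' categories (S, V) and indel categories (D, I), per structural domain, and
#' per species (the per-species weighted sum divided by the alignment length
#' is the species' weighted mutation ratio).
#'
#' @param classified output of [classify_alignment()] (or a list of
#'   `column_classification` plus a `column_domain` vector).
#' @param weights `category_weights` from [assign_weights()].
#' @param column_domain per-column domain labels (defaults to the ones
#'   carried by `classified`).
#' @return a `variability_profile`.
#' @export
weighted_profile <- function(classified, weights, column_domain = NULL) {
  cls <- if (!is.null(classified$classifications)) {
    classified$classifications
  } else classified
  if (is.null(column_domain)) column_domain <- classified$column_domain
  if (is.null(column_domain) || length(column_domain) != length(cls)) {
    stop("domain labels missing for some column(s)")
  }
  species <- names(cls[[1]]$labels)
  wt <- function(lab) {
    w <- unclass(weights)[lab]
    if (anyNA(w)) stop("no weight assigned for category ",
                       paste(unique(lab[is.na(w)]), collapse = " "))
    unname(w)
  }
  snp_total <- 0; indel_total <- 0
  dom_levels <- unique(column_domain)
  dom_snp <- setNames(numeric(length(dom_levels)), dom_levels)
  dom_indel <- dom_snp
  sp_sum <- setNames(numeric(length(species)), species)
  for (k in seq_along(cls)) {
    lab <- cls[[k]]$labels
    w <- wt(lab)
    is_snp <- lab %in% c("S", "V")
    is_indel <- lab %in% c("D", "I")
    snp_total <- snp_total + sum(w[is_snp])
    indel_total <- indel_total + sum(w[is_indel])
    d <- column_domain[k]
    dom_snp[d] <- dom_snp[d] + sum(w[is_snp])
    dom_indel[d] <- dom_indel[d] + sum(w[is_indel])
    sp_sum <- sp_sum + w
  }
  n_col <- length(cls)
  structure(list(
    snp_total = snp_total,
    indel_total = indel_total,
    domain_totals = data.frame(
      domain = dom_levels, snp = unname(dom_snp), indel = unname(dom_indel),
      stringsAsFactors = FALSE
    ),
    species_weighted = sp_sum,
    species_ratio = sp_sum / n_col,
    avg_ratio = mean(sp_sum / n_col),
    n_columns = n_col,
    n_species = length(species)
  ), class = "variability_profile")
}

#' @export
print.variability_profile <- function(x, ...) {
  cat("variability_profile:", x$n_species, "species x", x$n_columns,
      "columns\n")
  cat(sprintf("  weighted SNP total %.3f, indel total %.3f, avg ratio %.4f\n",
              x$snp_total, x$indel_total, x$avg_ratio))
  invisible(x)
}

#' Cohort-contrasted z-scores and variability categories
#'
#' Normalizes per-tRNA weighted variability within each cohort (family-wide
#' "Ci" and sublineage "Ht") and assigns the four contrast categories:
#' 1 = hypervariable in both, 2 = hypovariable in both, 3 = hyper in Ci /
#' hypo in Ht, 4 = hypo in Ci / hyper in Ht. Hyper/hypo follows the sign of
#' the z-score (z >= 0 is hyper); |z| >= 1 is flagged extreme, mirroring the
#' conventional +/-1 standard limits.
#'
#' @param totals_ci,totals_ht named per-tRNA numeric vectors over the same
#'   tRNA set.
#' @return data frame: `trna`, `z_ci`, `z_ht`, `category`, `extreme_ci`,
#'   `extreme_ht`.
#' @export
zscore_categorize <- function(totals_ci, totals_ht) {
  if (is.null(names(totals_ci)) || is.null(names(totals_ht)) ||
      !setequal(names(totals_ci), names(totals_ht))) {
    stop("both vectors must be named over the same tRNA set")
  }
  totals_ht <- totals_ht[names(totals_ci)]
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("degenerate cohort vector (zero SD)")
    (x - mean(x)) / s
  }
  z_ci <- zs(totals_ci); z_ht <- zs(totals_ht)
  hyper_ci <- z_ci >= 0; hyper_ht <- z_ht >= 0
  category <- ifelse(hyper_ci & hyper_ht, 1L,
              ifelse(!hyper_ci & !hyper_ht, 2L,
              ifelse(hyper_ci & !hyper_ht, 3L, 4L)))
  data.frame(
    trna = names(totals_ci),
    total_ci = unname(totals_ci), total_ht = unname(totals_ht),
    z_ci = unname(z_ci), z_ht = unname(z_ht),
    category = unname(category),
    extreme_ci = unname(abs(z_ci) >= 1), extreme_ht = unname(abs(z_ht) >= 1),
    stringsAsFactors = FALSE
  )
}

#' Cohort-contrasted variability over a set of gene alignments
#'
#' Runs the full substitution-quantification chain for every tRNA gene in
#' each cohort: columns are classified against the cohort's own dominant
#' bases, category totals are weighted (one weight table across all genes
#' with `weight_scope = "global"`, or per gene), and the per-tRNA average
#' weighted mutation ratios are z-score-contrasted between the family-wide
#' cohort (Ci) and the sublineage (Ht).
#'
#' @param aligs named list of `gene_alignment` objects (one per tRNA).
#' @param cohort data frame `species_id`, `in_family`, `in_sublineage`.
#' @param weight_scope `"global"` or `"per-gene"`.
#' @param substitution_only use the fixed transition/transversion weights.
#' @return list with per-cohort `profiles`, the `weights` used, and the
#'   `categories` data frame from [zscore_categorize()].
#' @export
quantify_variability <- function(aligs, cohort,
                                 weight_scope = c("global", "per-gene"),
                                 substitution_only = FALSE) {
  weight_scope <- match.arg(weight_scope)
  stopifnot(all(c("species_id", "in_family", "in_sublineage") %in%
                  names(cohort)))
  run_cohort <- function(members) {
    classified <- lapply(aligs, function(al) {
      sub <- al
      sub$matrix <- al$matrix[intersect(rownames(al$matrix), members), ,
                              drop = FALSE]
      classify_alignment(sub)
    })
    # the fixed transition/transversion weights apply whenever the data
    # hold no indel categories at all
    sub_only <- function(tot) {
      substitution_only || all(names(tot) %in% c("C", "S", "V"))
    }
    if (weight_scope == "global") {
      gtot <- Reduce(`+`, lapply(classified, `[[`, "totals"))
      gtot <- gtot[gtot > 0]
      w <- assign_weights(gtot, sub_only(gtot))
      weights <- rep(list(w), length(classified))
    } else {
      weights <- lapply(classified, function(cl) {
        tot <- cl$totals[cl$totals > 0]
        assign_weights(tot, sub_only(tot))
      })
    }
    profiles <- mapply(function(cl, w) weighted_profile(cl, w),
                       classified, weights, SIMPLIFY = FALSE)
    names(profiles) <- names(aligs)
    profiles
  }
  ci_members <- cohort$species_id[as.logical(cohort$in_family)]
  ht_members <- cohort$species_id[as.logical(cohort$in_sublineage)]
  if (!length(ht_members)) stop("empty sublineage cohort")
  if (!all(ht_members %in% ci_members)) {
    stop("sublineage (Ht) must be a subset of the family cohort (Ci)")
  }
  prof_ci <- run_cohort(ci_members)
  prof_ht <- run_cohort(ht_members)
  tot <- function(pr) vapply(pr, `[[`, numeric(1), "avg_ratio")
  list(
    profiles = list(ci = prof_ci, ht = prof_ht),
    categories = zscore_categorize(tot(prof_ci), tot(prof_ht))
  )
}

#' Long-format export of per-domain weighted variability
#'
#' @param profiles named list of `variability_profile` objects (per tRNA).
#' @return data frame `trna`, `domain`, `type` (snp/indel), `weighted`,
#'   ready for alluvial/boxplot tooling.
#' @export
profile_long <- function(profiles) {
  do.call(rbind, lapply(names(profiles), function(g) {
    dt <- profiles[[g]]$domain_totals
    data.frame(
      trna = g,
      domain = rep(dt$domain, 2L),
      type = rep(c("snp", "indel"), each = nrow(dt)),
      weighted = c(dt$snp, dt$indel),
      stringsAsFactors = FALSE
    )
  }))
}
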