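# Synthetic cohort generator.
#
# Emulates the statistical structure of a mitochondrial tRNA cohort study:
# 22 tRNA genes per species (one D-armless isotype, eight reverse-strand
# genes), 67-74 nt cloverleaf sequences evolved down a species tree with a
# transition/transversion ratio kappa, per-gene rate multipliers, and indels
# confined to loops (D- and V-loops elevated), plus CDS sequences evolved
# under the vertebrate mitochondrial code. Two nested cohorts (family-wide
# Ci and a monophyletic sublineage Ht) receive independently controllable
# rates so contrasting variability categories can be simulated. All output
# is a deterministic function of the seed.

# The 22 vertebrate mitochondrial tRNA isotypes in canonical genome order,
# with anticodons (DNA alphabet, 5'->3') and coding strand. Eight genes
# (trnQ, trnA, trnN, trnC, trnY, trnS-UGA, trnE, trnP) lie on the reverse
# strand; trnS-GCU lacks the D arm.
.MT_TRNAS <- data.frame(
  isotype = c("trnF", "trnV", "trnL-UAA", "trnI", "trnQ", "trnM", "trnW",
              "trnA", "trnN", "trnC", "trnY", "trnS-UGA", "trnD", "trnK",
              "trnG", "trnR", "trnH", "trnS-GCU", "trnL-UAG", "trnE",
              "trnT", "trnP"),
  anticodon = c("GAA", "TAC", "TAA", "GAT", "TTG", "CAT", "TCA",
                "TGC", "GTT", "GCA", "GTA", "TGA", "GTC", "TTT",
                "TCC", "TCG", "GTG", "GCT", "TAG", "TTC",
                "TGT", "TGG"),
  strand = c("forward", "forward", "forward", "forward", "reverse",
             "forward", "forward", "reverse", "reverse", "reverse",
             "reverse", "reverse", "forward", "forward", "forward",
             "forward", "forward", "forward", "forward", "reverse",
             "forward", "reverse"),
  armless = c(rep(FALSE, 17), TRUE, rep(FALSE, 4)),
  stringsAsFactors = FALSE
)

#' The 22 mitochondrial tRNA isotypes
#'
#' @return data frame with `isotype`, `anticodon` (DNA alphabet), `strand`
#'   and `armless` columns.
#' @export
trna_isotypes <- function() .MT_TRNAS

.LOOP_RANGE <- list(
  "D-loop" = c(3L, 10L), "V-loop" = c(4L, 6L), "T-loop" = c(7L, 9L),
  "An-loop" = c(7L, 7L)
)

#' Specification of a synthetic cohort
#'
#' Defaults reflect the study conditions the generator emulates: a
#' family-wide cohort with a nested sublineage of about a third of the
#' species, tRNA divergence of a few percent, transition bias kappa ~ 2.25
#' (between the purine and pyrimidine rate ratios typical of fish
#' mitogenomes), fish-mitogenome-like base composition, and indels
#' essentially restricted to the D- and V-loops.
#'
#' @param n_species number of species in the family cohort.
#' @param sublineage_fraction fraction of species forming the nested
#'   sublineage clade.
#' @param sublineage_depth height of the sublineage clade as a fraction of
#'   the total tree height (controls within-sublineage variation).
#' @param seed integer seed; all output is reproducible from it.
#' @param subst_rate expected substitutions per site along a root-to-tip
#'   path (the coalescent tree is rescaled to height 1).
#' @param kappa transition/transversion rate ratio of the mutation process.
#' @param base_freqs named A/C/G/T frequencies of root sequences.
#' @param rate_multipliers named per-isotype substitution-rate factors
#'   (applied on every branch).
#' @param ht_rate_multipliers named per-isotype extra factors applied only
#'   on branches inside the sublineage clade.
#' @param indel_events expected indel events per tRNA gene over the whole
#'   tree.
#' @param domain_indel_odds relative indel odds per loop domain.
#' @param layouts optional named list of per-isotype layout overrides
#'   (`d`, `dl`, `cc2`, `v`, `tl`); lengths outside the structural ranges
#'   are an error.
#' @param cds_genes named vector of CDS lengths in codons.
#' @param cds_subst_rate per-site substitution rate for CDS evolution.
#' @param cds_ns_accept acceptance probability of a nonsynonymous change
#'   (1 = no purifying selection).
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_species = 24, sublineage_fraction = 1 / 3,
                        sublineage_depth = 0.35,
                        seed = 1L,
                        subst_rate = 0.08, kappa = 2.25,
                        base_freqs = c(A = 0.254, C = 0.225,
                                       G = 0.238, T = 0.283),
                        rate_multipliers = NULL,
                        ht_rate_multipliers = NULL,
                        indel_events = 1.2,
                        domain_indel_odds = c("D-loop" = 1, "V-loop" = 0.8,
                                              "T-loop" = 0.05),
                        layouts = NULL,
                        cds_genes = c(COX1 = 120, ND5 = 120),
                        cds_subst_rate = 0.04, cds_ns_accept = 0.2) {
  mult <- setNames(rep(1, nrow(.MT_TRNAS)), .MT_TRNAS$isotype)
  if (!is.null(rate_multipliers)) mult[names(rate_multipliers)] <- rate_multipliers
  hmult <- setNames(rep(1, nrow(.MT_TRNAS)), .MT_TRNAS$isotype)
  if (!is.null(ht_rate_multipliers)) {
    hmult[names(ht_rate_multipliers)] <- ht_rate_multipliers
  }
  if (any(mult <= 0) || any(hmult <= 0)) stop("rate multipliers must be > 0")
  if (n_species < 6) stop("need at least 6 species")
  if (sublineage_fraction <= 0 || sublineage_fraction >= 1) {
    stop("sublineage_fraction must be in (0, 1)")
  }
  base_freqs <- base_freqs[.BASES] / sum(base_freqs)
  if (!is.null(layouts)) {
    for (iso in names(layouts)) {
      ly <- layouts[[iso]]
      chk <- function(key, rng, what) {
        if (!is.null(ly[[key]]) && !ly[[key]] %in% rng) {
          stop(what, " must be ", min(rng), "-", max(rng),
               if (key %in% c("d")) " bp" else " nt", " (", iso, ")")
        }
      }
      chk("d", 3:4, "D-stem")
      chk("dl", 3:10, "D-loop")
      chk("v", 4:6, "V-loop")
      chk("tl", 7:9, "T-loop")
    }
  }
  structure(list(
    n_species = as.integer(n_species),
    sublineage_fraction = sublineage_fraction,
    sublineage_depth = sublineage_depth, seed = as.integer(seed),
    subst_rate = subst_rate, kappa = kappa, base_freqs = base_freqs,
    rate_multipliers = mult, ht_rate_multipliers = hmult,
    indel_events = indel_events, domain_indel_odds = domain_indel_odds,
    layouts = layouts, cds_genes = cds_genes,
    cds_subst_rate = cds_subst_rate, cds_ns_accept = cds_ns_accept
  ), class = "cohort_spec")
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

# mutate base vector in place: sites hit with prob p; transition with
# probability kappa / (kappa + 2). Substitutions at stem positions are
# compensatory: the pairing partner (given in `partner`, NA for loop sites)
# is set to the Watson-Crick complement, as mt-tRNA stems evolve under
# pairing constraints.
.mutate_sites <- function(bases, mutable, p, kappa, partner = NULL) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  hit <- mutable[stats::runif(length(mutable)) < p]
  for (i in hit) {
    b <- bases[i]
    bases[i] <- if (stats::runif(1) < kappa / (kappa + 2)) {
      .TRANSITION[[b]]
    } else {
      sample(.TRANSVERSIONS[[b]], 1L)
    }
    if (!is.null(partner) && !is.na(partner[i])) {
      bases[partner[i]] <- comp[[bases[i]]]
    }
  }
  bases
}

# sample a layout for an isotype under the structural constraints
.sample_layout <- function(armless, override = NULL) {
  if (armless) {
    repeat {
      v <- sample(4:16, 1L); tl <- sample(7:9, 1L)
      cc <- sample(3:8, 1L)
      L <- 42L + cc + v + tl
      if (L >= 67L && L <= 74L) {
        return(list(armless = TRUE, a = 7L, cc = cc, an = 5L, anl = 7L,
                    v = v, t = 5L, tl = tl))
      }
    }
  }
  o <- function(x, default) if (!is.null(override[[x]])) override[[x]] else default
  repeat {
    d <- o("d", sample(3:4, 1L)); dl <- o("dl", sample(3:10, 1L))
    cc2 <- o("cc2", 1L)
    v <- o("v", sample(4:6, 1L)); tl <- o("tl", sample(7:9, 1L))
    L <- 44L + 2L * d + dl + cc2 + v + tl
    if (L >= 67L && L <= 74L) {
      return(list(armless = FALSE, a = 7L, cc1 = 2L, d = d, dl = dl,
                  cc2 = cc2, an = 5L, anl = 7L, v = v, t = 5L, tl = tl))
    }
    if (!is.null(override)) {
      stop("layout override for lengths outside the structural ranges")
    }
  }
}

# build a root tRNA sequence for a layout: random loops, perfectly paired
# stems, anticodon centered in the An-loop. The first and last D-loop
# positions are fixed to T (the conserved dihydrouridine residues flanking
# real D-loops) and kept immutable, which also keeps the D-stem boundary
# structurally unambiguous.
.root_trna <- function(layout, anticodon, base_freqs) {
  labels <- .layout_labels(layout)
  L <- length(labels)
  bases <- sample(.BASES, L, replace = TRUE, prob = base_freqs)
  pairs <- .stem_pairs_from_labels(labels)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  bases[pairs$pos3] <- comp[bases[pairs$pos5]]
  anl <- which(labels == "An-loop")
  ac_pos <- anl[3:5]
  bases[ac_pos] <- .chars(anticodon)
  fixed <- ac_pos
  # resample a stem 5' strand until no two bases at distance 1 or 2 are
  # equal; an invariant stem with this property cannot be re-paired by any
  # one- or two-position shift of the stem boundary, which keeps the
  # template layout identifiable in every descendant sequence
  destutter <- function(idx) {
    for (k in seq_along(idx)[-1]) {
      prev <- bases[idx[max(1L, k - 2L):(k - 1L)]]
      while (bases[idx[k]] %in% prev) {
        bases[idx[k]] <<- sample(.BASES, 1L, prob = base_freqs)
      }
    }
  }
  pin_stem <- function(stem) {
    s5 <- which(labels == paste0(stem, "-stem5'"))
    if (!length(s5)) return(integer(0))
    destutter(s5)
    s3 <- which(labels == paste0(stem, "-stem3'"))
    bases[s3] <<- comp[bases[rev(s5)]]
    c(s5, s3)
  }
  dloop <- which(labels == "D-loop")
  if (length(dloop)) {
    du_pos <- range(dloop)
    bases[du_pos] <- "T"
    # the D and T arms are invariant (the shortest stem and the least
    # polymorphic arm, respectively); substitutions fall on the A- and
    # An-stems (compensatory) and on the loops
    fixed <- c(fixed, du_pos, pin_stem("D"), pin_stem("T"))
  } else {
    fixed <- c(fixed, pin_stem("T"))
  }
  partner <- rep(NA_integer_, L)
  partner[pairs$pos5] <- pairs$pos3
  partner[pairs$pos3] <- pairs$pos5
  list(bases = bases, labels = labels, ac_pos = ac_pos,
       fixed = fixed, partner = partner)
}

# tips below a node (node may be a tip)
.clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= n])
    stack <- c(stack, ch[ch > n])
  }
  out
}

# all nodes (tips + internal) within a clade, including its root node
.clade_nodes <- function(tree, node) {
  n <- length(tree$tip.label)
  out <- node
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, ch)
    stack <- c(stack, ch[ch > n])
  }
  out
}

#' Generate a synthetic nested-cohort tRNA + CDS data set
#'
#' @param spec a `cohort_spec`.
#' @param dir optional directory; when given, per-gene FASTA, aligned FASTA,
#'   the cohort CSV, CDS FASTA, per-species genome FASTA and a `truth.json`
#'   are written there.
#' @return a `trna_cohort`: `tree` (phylo), `cohort` (membership table),
#'   `genes` (TRNAGene data frame with per-species genome coordinates),
#'   `genomes` (named sequences), `alignments` (true per-gene
#'   `gene_alignment`s), `cds` (per-gene aligned matrices), and `truth`
#'   (layouts, rates, sublineage, newick).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_species
  tree <- ape::rcoal(n, tip.label = sprintf("sp%02d", seq_len(n)))
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree <- ape::reorder.phylo(tree, "cladewise")

  # sublineage = internal clade closest in size to the target fraction,
  # rescaled so the clade spans `sublineage_depth` of the total tree height
  # (so within-sublineage variation exists at a controlled level)
  target <- max(2L, round(n * spec$sublineage_fraction))
  internal <- (n + 2L):(n + tree$Nnode)        # exclude the root
  sizes <- vapply(internal, function(nd) length(.clade_tips(tree, nd)),
                  integer(1))
  depths <- ape::node.depth.edgelength(tree)
  ok <- sizes >= 2L & sizes <= n - 2L
  okn <- internal[ok]; oks <- sizes[ok]
  ch <- spec$sublineage_depth
  # prefer clades whose parent sits shallow enough to leave the sublineage
  # a distinct stem branch (>= 8% of the tree height)
  pdep <- depths[tree$edge[match(okn, tree$edge[, 2L]), 1L]]
  feas <- pdep <= 1 - ch - 0.08
  if (any(feas)) { okn <- okn[feas]; oks <- oks[feas]; pdep <- pdep[feas] }
  ht_node <- okn[which.min(abs(oks - target))]
  par_depth <- depths[tree$edge[match(ht_node, tree$edge[, 2L]), 1L]]
  ch <- min(ch, (1 - par_depth) * 0.9)         # keep a positive stem edge
  inner <- setdiff(.clade_nodes(tree, ht_node), ht_node)
  inner_edges <- which(tree$edge[, 2L] %in% inner)
  h_old <- 1 - depths[ht_node]
  if (h_old > 0 && length(inner_edges)) {
    tree$edge.length[inner_edges] <- tree$edge.length[inner_edges] * ch / h_old
  }
  stem <- match(ht_node, tree$edge[, 2L])
  tree$edge.length[stem] <- (1 - ch) - par_depth
  ht_tips <- sort(.clade_tips(tree, ht_node))
  ht_species <- tree$tip.label[ht_tips]
  ht_nodes <- .clade_nodes(tree, ht_node)
  cohort <- data.frame(
    species_id = tree$tip.label,
    in_family = TRUE,
    in_sublineage = tree$tip.label %in% ht_species,
    stringsAsFactors = FALSE
  )

  aligs <- list(); layouts <- list()
  for (g in seq_len(nrow(.MT_TRNAS))) {
    iso <- .MT_TRNAS$isotype[g]
    # resample until the root is structurally unambiguous (template
    # annotation of the root recovers the intended layout)
    for (try in 1:50) {
      layout <- .sample_layout(.MT_TRNAS$armless[g], spec$layouts[[iso]])
      root <- .root_trna(layout, .MT_TRNAS$anticodon[g], spec$base_freqs)
      chk <- tryCatch(annotate_domains(list(
        sequence = paste(root$bases, collapse = ""),
        anticodon = .MT_TRNAS$anticodon[g]
      )), error = function(e) NULL)
      if (!is.null(chk) && identical(chk$domain_of, root$labels)) break
    }
    layouts[[iso]] <- root$labels
    mutable <- setdiff(seq_along(root$bases), root$fixed)
    mult <- spec$rate_multipliers[[iso]]
    hmult <- spec$ht_rate_multipliers[[iso]]

    # evolve down the tree (edges are in preorder)
    node_seq <- vector("list", n + tree$Nnode)
    node_seq[[n + 1L]] <- root$bases
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      rate <- spec$subst_rate * mult * tree$edge.length[e]
      if (ch %in% ht_nodes) rate <- rate * hmult
      node_seq[[ch]] <- .mutate_sites(node_seq[[par]], mutable,
                                      min(rate, 0.75), spec$kappa,
                                      partner = root$partner)
    }
    mat <- do.call(rbind, node_seq[seq_len(n)])
    rownames(mat) <- tree$tip.label
    col_dom <- root$labels

    # indel events: whole-column insertions/deletions in loops only
    n_ev <- stats::rpois(1L, spec$indel_events)
    odds <- spec$domain_indel_odds
    for (ev in seq_len(n_ev)) {
      for (try in 1:20) {
        e <- sample.int(nrow(tree$edge), 1L, prob = tree$edge.length)
        affected <- tree$tip.label[.clade_tips(tree, tree$edge[e, 2L])]
        dom <- sample(names(odds), 1L, prob = odds)
        rng <- .LOOP_RANGE[[dom]]
        cols_all <- which(col_dom == dom)
        cols <- if (dom == "D-loop" && length(cols_all) > 2L) {
          cols_all[-c(1L, length(cols_all))]   # conserved boundary residues
        } else cols_all
        if (!length(cols)) next
        loop_len <- rowSums(mat[affected, cols_all, drop = FALSE] != "-")
        tot_len <- rowSums(mat[affected, , drop = FALSE] != "-")
        type <- sample(c("del", "ins"), 1L)
        if (type == "del") {
          if (any(loop_len <= rng[1]) || any(tot_len <= 67L)) next
          col <- sample(rep(cols, 2L), 1L)[1]   # rep() guards length-1 sample
          if (all(mat[affected, col] == "-")) next
          mat[affected, col] <- "-"
        } else {
          if (any(loop_len >= rng[2]) || any(tot_len >= 74L)) next
          col <- sample(rep(cols, 2L), 1L)[1]
          newcol <- rep("-", n)
          newcol[match(affected, rownames(mat))] <-
            sample(.BASES, 1L, prob = spec$base_freqs)
          mat <- cbind(mat[, seq_len(col), drop = FALSE], newcol,
                       mat[, -seq_len(col), drop = FALSE])
          rownames(mat) <- tree$tip.label
          col_dom <- append(col_dom, dom, after = col)
        }
        break
      }
    }
    colnames(mat) <- NULL
    aligs[[iso]] <- structure(
      list(isotype = iso, matrix = mat, column_domain = col_dom,
           length = ncol(mat)),
      class = "gene_alignment"
    )
  }

  # TRNAGene table + per-species genome assembly
  genes <- list(); genomes <- setNames(character(n), tree$tip.label)
  for (sp in tree$tip.label) {
    genome <- paste(sample(.BASES, 20L, replace = TRUE,
                           prob = spec$base_freqs), collapse = "")
    for (g in seq_len(nrow(.MT_TRNAS))) {
      iso <- .MT_TRNAS$isotype[g]
      row <- aligs[[iso]]$matrix[sp, ]
      seq <- paste(row[row != "-"], collapse = "")
      insert <- if (.MT_TRNAS$strand[g] == "reverse") revcomp(seq) else seq
      start <- nchar(genome) + 1L
      genome <- paste0(genome, insert)
      end <- nchar(genome)
      genome <- paste0(genome, paste(sample(.BASES, 10L, replace = TRUE,
                                            prob = spec$base_freqs),
                                     collapse = ""))
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = paste(sp, iso, sep = "_"), species_id = sp, isotype = iso,
        anticodon = .MT_TRNAS$anticodon[g], strand = .MT_TRNAS$strand[g],
        start = start, end = end, sequence = seq, stringsAsFactors = FALSE
      )
    }
    genomes[sp] <- genome
  }
  genes <- do.call(rbind, genes)

  # CDS evolution under the vertebrate mitochondrial code
  code <- .mito_code()
  stops <- names(code)[code == "*"]
  codons_ok <- setdiff(names(code), stops)
  cds <- list()
  for (cg in names(spec$cds_genes)) {
    n_codon <- spec$cds_genes[[cg]]
    root_codons <- c("ATG", sample(codons_ok, n_codon - 2L, replace = TRUE),
                     "TAA")
    root_b <- unlist(strsplit(root_codons, ""))
    Lc <- length(root_b)
    mutable <- 4:(Lc - 3L)                     # start and stop codons fixed
    node_seq <- vector("list", n + tree$Nnode)
    node_seq[[n + 1L]] <- root_b
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      p <- min(spec$cds_subst_rate * tree$edge.length[e], 0.75)
      bases <- node_seq[[par]]
      hit <- mutable[stats::runif(length(mutable)) < p]
      for (i in hit) {
        old <- bases[i]
        newb <- if (stats::runif(1) < spec$kappa / (spec$kappa + 2)) {
          .TRANSITION[[old]]
        } else sample(.TRANSVERSIONS[[old]], 1L)
        ci <- (i - 1L) %/% 3L
        cod <- bases[(ci * 3L + 1L):(ci * 3L + 3L)]
        cod[(i - 1L) %% 3L + 1L] <- newb
        newcod <- paste(cod, collapse = "")
        if (code[[newcod]] == "*") next                     # no internal stops
        oldcod <- paste(bases[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
        if (code[[newcod]] != code[[oldcod]] &&
            stats::runif(1) >= spec$cds_ns_accept) next     # purifying filter
        bases[i] <- newb
      }
      node_seq[[ch]] <- bases
    }
    m <- do.call(rbind, node_seq[seq_len(n)])
    rownames(m) <- tree$tip.label
    cds[[cg]] <- m
  }

  out <- structure(list(
    spec = spec, tree = tree, cohort = cohort, genes = genes,
    genomes = genomes, alignments = aligs, cds = cds,
    truth = list(
      newick = ape::write.tree(tree),
      ht_species = ht_species,
      layouts = layouts,
      rate_multipliers = spec$rate_multipliers,
      ht_rate_multipliers = spec$ht_rate_multipliers
    )
  ), class = "trna_cohort")
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' True per-species domain labels from a generated alignment
#'
#' @param cohort a `trna_cohort`.
#' @param isotype gene name.
#' @param species species id.
#' @return character vector of domain labels, one per (non-gap) sequence
#'   position.
#' @export
true_domains <- function(cohort, isotype, species) {
  al <- cohort$alignments[[isotype]]
  row <- al$matrix[species, ]
  al$column_domain[row != "-"]
}

#' @export
print.trna_cohort <- function(x, ...) {
  cat("trna_cohort:", x$spec$n_species, "species (",
      sum(x$cohort$in_sublineage), "in sublineage ),",
      length(x$alignments), "tRNA genes,", length(x$cds), "CDS\n")
  invisible(x)
}
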