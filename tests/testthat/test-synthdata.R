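test_that("generated cohorts respect the structural study conditions", {
  co <- generate_cohort(cohort_spec(n_species = 10, seed = 9))
  expect_equal(length(co$alignments), 22L)
  expect_equal(nrow(co$cohort), 10L)
  expect_true(all(co$cohort$in_sublineage %in% c(TRUE, FALSE)))
  expect_gte(sum(co$cohort$in_sublineage), 2L)
  # gene lengths within the observed mitochondrial range
  expect_true(all(nchar(co$genes$sequence) >= 67 &
                    nchar(co$genes$sequence) <= 74))
  # eight reverse-strand genes per species, fixed isotype set
  for (sp in co$cohort$species_id[1:3]) {
    g <- co$genes[co$genes$species_id == sp, ]
    expect_equal(nrow(g), 22L)
    expect_equal(sum(g$strand == "reverse"), 8L)
    expect_setequal(g$isotype, trna_isotypes()$isotype)
    # anticodon is a substring of the gene product
    expect_true(all(mapply(grepl, g$anticodon, g$sequence)))
  }
  # exactly one D-armless isotype
  armless <- vapply(names(co$alignments), function(iso) {
    !"D-loop" %in% co$alignments[[iso]]$column_domain
  }, logical(1))
  expect_equal(names(which(armless)), "trnS-GCU")
  # genome slice matches the gene (reverse genes are reverse-complemented)
  g <- co$genes[co$genes$species_id == "sp01", ]
  for (k in which(g$strand == "reverse")[1:3]) {
    slice <- substr(co$genomes[["sp01"]], g$start[k], g$end[k])
    expect_equal(trnadyn:::revcomp(slice), g$sequence[k])
    expect_equal(trnadyn:::revcomp(trnadyn:::revcomp(slice)), slice)
  }
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(cohort_spec(n_species = 8, seed = 123))
  b <- generate_cohort(cohort_spec(n_species = 8, seed = 123))
  expect_identical(a$genes, b$genes)
  expect_identical(lapply(a$alignments, `[[`, "matrix"),
                   lapply(b$alignments, `[[`, "matrix"))
  expect_identical(a$cds, b$cds)
  c2 <- generate_cohort(cohort_spec(n_species = 8, seed = 124))
  expect_false(identical(a$genes$sequence, c2$genes$sequence))
})

test_that("zero rates reproduce the root sequence everywhere", {
  sp <- cohort_spec(n_species = 8, seed = 4, subst_rate = 1e-12,
                    indel_events = 0, cds_subst_rate = 1e-12)
  co <- generate_cohort(sp)
  for (iso in c("trnF", "trnC", "trnS-GCU")) {
    seqs <- unique(co$genes$sequence[co$genes$isotype == iso])
    expect_equal(length(seqs), 1L, label = iso)
  }
  expect_equal(length(unique(apply(co$cds[["COX1"]], 1, paste,
                                   collapse = ""))), 1L)
})

test_that("layout overrides outside the structural ranges are rejected", {
  expect_error(cohort_spec(layouts = list(trnF = list(dl = 12))), "D-loop")
  expect_error(cohort_spec(layouts = list(trnF = list(v = 9))), "V-loop")
  expect_error(cohort_spec(sublineage_fraction = 1.2), "fraction")
  expect_error(cohort_spec(rate_multipliers = c(trnC = -1)), "> 0")
})

test_that("indels are confined to loops and CDS evolve without internal stops", {
  co <- generate_cohort(cohort_spec(n_species = 10, seed = 15,
                                    indel_events = 4))
  for (iso in names(co$alignments)) {
    al <- co$alignments[[iso]]
    gapcols <- which(colSums(al$matrix == "-") > 0)
    expect_true(all(al$column_domain[gapcols] %in%
                      c("D-loop", "V-loop", "T-loop")), label = iso)
  }
  code <- Biostrings::getGeneticCode("2")
  for (cg in names(co$cds)) {
    for (sp in rownames(co$cds[[cg]])) {
      s <- co$cds[[cg]][sp, ]
      codons <- apply(matrix(s, nrow = 3), 2, paste, collapse = "")
      aa <- unname(code[codons])
      expect_false(any(aa[-length(aa)] == "*"), label = paste(cg, sp))
      expect_equal(aa[length(aa)], "*")
    }
  }
})

test_that("simulated transition bias is recovered from ~10 kb of tRNA alignment", {
  co <- generate_cohort(cohort_spec(n_species = 10, seed = 77,
                                    subst_rate = 0.15, kappa = 4,
                                    base_freqs = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                                    indel_events = 0))
  # concatenate all 22 gene alignments (~70 nt x 22 x 10 rows ~ 15 kb cells)
  mats <- lapply(co$alignments, `[[`, "matrix")
  big <- do.call(cbind, lapply(mats, function(m) m[co$cohort$species_id, ]))
  tb <- suppressWarnings(tstv_bias(big))  # a saturated pair may be skipped
  # K80-style process with kappa = 4 at equal frequencies: R = kappa / 2
  expect_lt(abs(tb$R - 2) / 2, 0.15)
})

test_that("worked-example fixtures satisfy every printed constraint", {
  # trnC: 66 columns, 7 transition-only polymorphic sites, 4 from C. zillii
  ex <- worked_example("trnC_egypt")
  m <- ex$alignment$matrix
  expect_equal(dim(m), c(3L, 66L))
  poly <- which(apply(m, 2, function(cl) length(unique(cl)) > 1))
  expect_equal(poly, c(16L, 19L, 20L, 25L, 27L, 47L, 62L))
  expect_equal(66L - length(poly), 59L)   # 59 identical sites = 89.4%
  for (j in poly) {
    b <- unique(m[, j])
    expect_equal(length(b), 2L)
    expect_true(trnadyn:::is_transition(b[1], b[2]))
  }
  minority <- vapply(poly, function(j) {
    names(which.min(table(factor(m[, j]))[table(factor(m[, j])) > 0]))
  }, "")
  carriers <- vapply(poly, function(j) {
    tb <- table(m[, j])
    rownames(m)[m[, j] == names(tb)[which.min(tb)]]
  }, "")
  expect_equal(sum(carriers == "C_zillii"), 4L)
  # D-loop of 3 nt; wobble pairs T5.G61 and G10.T20 in the backbone
  expect_equal(unname(ex$annotation$loop_lengths["D-loop"]), 3L)
  mm <- pairing_mismatches(paste(ex$annotation$bases, collapse = ""),
                           ex$annotation)
  expect_true(any(mm$pos5 == 5 & mm$pos3 == 61 & mm$base5 == "T" &
                    mm$base3 == "G" & mm$wobble))
  expect_true(any(mm$pos5 == 10 & mm$pos3 == 20 & mm$base5 == "G" &
                    mm$base3 == "T" & mm$wobble))

  # trnD: 73 columns, 64 identical, one three-variant site at 17,
  # substitution types as printed, C50.A64 mispair private to C. zillii
  ex2 <- worked_example("trnD_egypt")
  m2 <- ex2$alignment$matrix
  expect_equal(dim(m2), c(3L, 73L))
  poly2 <- which(apply(m2, 2, function(cl) length(unique(cl)) > 1))
  expect_equal(poly2, c(15L, 17L, 20L, 21L, 56L, 57L, 59L, 64L, 73L))
  expect_equal(73L - length(poly2), 64L)  # 87.7% conservation
  nvar <- vapply(poly2, function(j) length(unique(m2[, j])), integer(1))
  expect_equal(poly2[nvar == 3], 17L)
  pairtype <- function(j) sort(unique(m2[, j]))
  expect_equal(pairtype(15), c("A", "G"))
  expect_equal(pairtype(20), c("C", "T"))
  expect_equal(pairtype(21), c("C", "T"))
  expect_equal(pairtype(56), c("A", "T"))  # the single transversion
  expect_equal(pairtype(57), c("A", "G"))
  expect_equal(pairtype(59), c("A", "G"))
  expect_equal(pairtype(64), c("A", "G"))
  expect_equal(pairtype(73), c("A", "G"))
  mmz <- pairing_mismatches(paste(m2["C_zillii", ], collapse = ""),
                            ex2$annotation)
  expect_true(any(mmz$pos5 == 50 & mmz$pos3 == 64 & mmz$base5 == "C" &
                    mmz$base3 == "A"))
  expect_error(worked_example("nope"))
})

test_that("true domain labels are exposed per species", {
  co <- generate_cohort(cohort_spec(n_species = 8, seed = 33))
  td <- true_domains(co, "trnF", "sp01")
  g <- co$genes[co$genes$isotype == "trnF" & co$genes$species_id == "sp01", ]
  expect_equal(length(td), nchar(g$sequence))
  expect_equal(td[1], "A-stem5'")
  expect_equal(td[length(td)], "discriminator")
})
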