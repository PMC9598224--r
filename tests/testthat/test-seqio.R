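test_that("FASTA round trip preserves sequences and names", {
  co <- generate_cohort(cohort_spec(n_species = 8, seed = 10))
  seqs <- setNames(co$genes$sequence[1:22], co$genes$gene_id[1:22])
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_identical(back, seqs)
  # gapped alignment round trip
  al <- co$alignments[["trnY"]]
  path2 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(al, path2)
  back2 <- read_fasta(path2)
  expect_identical(unname(back2), unname(alignment_strings(al)))
})

test_that("structure files are validated line by line", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("g1\t(((...)))", "g2\t..((..))."), path)
  st <- read_structure_file(path)
  expect_equal(names(st), c("g1", "g2"))
  writeLines(c("g1\t(((...))"), path)
  expect_error(read_structure_file(path), "line 1")
  writeLines(c("g1\t(((...)))", "g2"), path)
  expect_error(read_structure_file(path), "line 2")
  # length mismatch against the named gene is a hard error
  genes <- data.frame(gene_id = "g1", sequence = "ACGTACGTA",
                      stringsAsFactors = FALSE)
  expect_silent(validate_structures(c(g1 = "(((...)))"), genes))
  expect_error(validate_structures(c(g1 = "((...))"), genes), "g1")
})

test_that("cohort tables enforce membership invariants", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(species_id = c("s1", "s2", "s3"),
                   in_family = c(TRUE, TRUE, TRUE),
                   in_sublineage = c(FALSE, TRUE, FALSE))
  write.csv(df, path, row.names = FALSE)
  back <- read_cohort_table(path)
  expect_equal(back$species_id, df$species_id)
  expect_equal(back$in_sublineage, df$in_sublineage)
  df2 <- df; df2$in_family[2] <- FALSE
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_cohort_table(path), "subset")
  df3 <- rbind(df, df[1, ])
  write.csv(df3, path, row.names = FALSE)
  expect_error(read_cohort_table(path), "duplicated")
})

test_that("GenBank extraction normalizes strand and resolves duplicate isotypes", {
  co <- generate_cohort(cohort_spec(n_species = 8, seed = 20))
  sp <- "sp01"
  g <- co$genes[co$genes$species_id == sp, ]
  feats <- data.frame(type = "tRNA", start = g$start, end = g$end,
                      strand = g$strand,
                      product = vapply(g$isotype, aa1_to_product, ""),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank_record(path, "SYN00001", co$genomes[[sp]], feats)
  recs <- read_genbank(path)
  expect_equal(length(recs), 1L)
  expect_equal(recs[[1]]$accession, "SYN00001")
  expect_equal(recs[[1]]$sequence, co$genomes[[sp]])
  got <- extract_trna_genes(recs[[1]])
  expect_equal(nrow(got), 22L)
  expect_setequal(got$isotype, trna_isotypes()$isotype)
  expect_equal(sum(got$strand == "reverse"), 8L)
  # sequences come back 5'->3' regardless of strand
  key <- paste(g$isotype)
  expect_equal(got$sequence[match(key, got$isotype)], g$sequence)
  # forward-strand gene equals the genome slice verbatim
  fw <- got[got$strand == "forward", ][1, ]
  expect_equal(fw$sequence,
               substr(recs[[1]]$sequence, fw$start, fw$end))
  # the L/L and S/S duplicates carry distinct anticodons
  expect_equal(sort(got$anticodon[got$isotype %in% c("trnL-UAA", "trnL-UAG")]),
               c("TAA", "TAG"))
  expect_equal(sort(got$anticodon[got$isotype %in% c("trnS-UGA", "trnS-GCU")]),
               c("GCT", "TGA"))
})

test_that("records with missing isotypes are flagged incomplete", {
  co <- generate_cohort(cohort_spec(n_species = 8, seed = 20))
  g <- co$genes[co$genes$species_id == "sp02", ][1:10, ]
  feats <- data.frame(type = "tRNA", start = g$start, end = g$end,
                      strand = g$strand,
                      product = vapply(g$isotype, aa1_to_product, ""),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank_record(path, "SYN00002", co$genomes[["sp02"]], feats)
  rec <- read_genbank(path)[[1]]
  expect_warning(got <- extract_trna_genes(rec), "incomplete")
  expect_true(isTRUE(attr(got, "incomplete")))
})

test_that("QC filters drop incomplete, outlier and ambiguous records", {
  co <- generate_cohort(cohort_spec(n_species = 10, seed = 30))
  genes <- co$genes
  # sp01 loses one isotype; sp02 gets an absurd gene length; sp03 Ns
  genes <- genes[!(genes$species_id == "sp01" & genes$isotype == "trnK"), ]
  genes$sequence[genes$species_id == "sp02" & genes$isotype == "trnF"] <-
    strrep("ACGT", 40)
  idx <- genes$species_id == "sp03" & genes$isotype == "trnC"
  genes$sequence[idx] <- paste0(strrep("N", 10),
                                substr(genes$sequence[idx], 11, 100))
  # sd_mult = 2: a single outlier among 10 species cannot exceed 3 SD
  # (the maximal z of one outlier is (n-1)/sqrt(n) ~ 2.85)
  qc <- qc_filter_genes(genes, sd_mult = 2)
  expect_true(all(c("sp01", "sp03") %in% qc$removed$species_id))
  expect_true("sp02" %in% qc$removed$species_id)
  expect_false(any(qc$kept$species_id %in% qc$removed$species_id))
  # untouched species pass
  expect_true("sp04" %in% qc$kept$species_id)
})

test_that("write_cohort emits the standard files and a readable truth table", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_species = 8, seed = 44), dir = dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "trnF.fasta")))
  expect_true(file.exists(file.path(dir, "trnF.aln.fasta")))
  expect_true(file.exists(file.path(dir, "COX1.cds.fasta")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$ht_species), co$truth$ht_species)
  back <- read_cohort_table(file.path(dir, "cohort.csv"))
  expect_equal(back$species_id, co$cohort$species_id)
  fa <- read_fasta(file.path(dir, "trnF.fasta"))
  g <- co$genes[co$genes$isotype == "trnF", ]
  expect_equal(unname(fa[g$species_id]), g$sequence)
})
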