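test_that("protein-change tokens parse, round-trip and reject bad input", {
  p <- parse_protein_change(c("V353I", "R2K"))
  expect_equal(p$wt_aa, c("V", "R"))
  expect_equal(p$position, c(353L, 2L))
  expect_equal(p$mut_aa, c("I", "K"))
  expect_equal(format_protein_change(p$wt_aa, p$position, p$mut_aa),
               c("V353I", "R2K"))

  expect_error(parse_protein_change("A5A"), "wild-type equals mutant")
  expect_error(parse_protein_change("X12Y"), "non-canonical")
  expect_error(parse_protein_change("V0I"), "position")
  expect_error(parse_protein_change("353I"), "malformed")
})

test_that("greek-letter gene symbols normalize to HGNC style", {
  expect_equal(normalize_gene_symbol(c("TUBα1A", "TUBß8", "TUBγ1", "tubb3")),
               c("TUBA1A", "TUBB8", "TUBG1", "TUBB3"))
})

test_that("variant loading validates against the registry and logs rejects", {
  reg <- toy_registry(c(T1 = "MAVCK", T2 = "MRRRW"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("isotype,protein_change",
               "T1,A2G",          # valid
               "T1,C4W",          # valid
               "T2,R3K",          # valid
               "T1,V2G",          # wt mismatch (registry has A at 2)
               "TX,A2G"),         # unknown isotype
             f)
  v <- suppressMessages(load_variant_table(f, "pathogenic", reg))
  expect_equal(nrow(v), 3)
  expect_equal(v$position, c(2L, 4L, 3L))
  rej <- attr(v, "rejects")
  expect_equal(nrow(rej), 2)
  expect_match(rej$reason[1], "wild-type mismatch")
  expect_match(rej$reason[2], "unknown isotype")
})

test_that("deduplication removes shared substitutions from both labels and is idempotent", {
  reg <- toy_registry(c(T1 = random_seq(50, 11)))
  path <- make_variants_df(reg, "T1", 1:10, label = "pathogenic")
  gnom <- make_variants_df(reg, "T1", 9:18, label = "gnomad")  # 9,10 shared
  cat1 <- variant_catalog(rbind(path, gnom), reg)
  dd <- deduplicate_overlaps(cat1)
  expect_equal(attr(dd, "n_removed"), 4)
  expect_equal(sum(dd$variants$label == "pathogenic"), 8)
  expect_equal(sum(dd$variants$label == "gnomad"), 8)
  expect_false(any(dd$variants$position %in% c(9, 10)))

  dd2 <- deduplicate_overlaps(dd)
  expect_identical(dd2$variants, dd$variants)

  # disjoint sets are untouched
  cat2 <- variant_catalog(rbind(make_variants_df(reg, "T1", 1:5),
                                make_variants_df(reg, "T1", 6:10, label = "gnomad")),
                          reg)
  expect_identical(deduplicate_overlaps(cat2)$variants, cat2$variants)

  # same site, different mutant residue: distinct records, both survive
  a <- make_variants_df(reg, "T1", 3, mut = "G")
  b <- make_variants_df(reg, "T1", 3, mut = "W", label = "gnomad")
  cat3 <- variant_catalog(rbind(a, b), reg)
  expect_equal(nrow(deduplicate_overlaps(cat3)$variants), 2)
})

test_that("published per-isotype counts drive eligibility thresholds", {
  reg <- isotype_registry()
  cat1 <- make_variant_catalog(1, reg)
  counts <- table(cat1$variants$isotype[cat1$variants$label == "pathogenic"])
  expect_equal(unname(counts["TUBA1A"]), 67)

  expect_setequal(eligible_isotypes(cat1, 10),
                  c("TUBA1A", "TUBB2B", "TUBB3", "TUBB4A", "TUBB8"))
  expect_setequal(eligible_isotypes(cat1, 5),
                  c("TUBA1A", "TUBB2B", "TUBB3", "TUBB4A", "TUBB8",
                    "TUBB1", "TUBB5", "TUBA4A", "TUBG1"))

  # monotone: raising the floor never adds an isotype
  sets <- lapply(1:12, function(m) eligible_isotypes(cat1, m))
  for (m in 2:12)
    expect_true(all(sets[[m]] %in% sets[[m - 1]]))
})

test_that("label counts after load + dedup match an independent line-count oracle", {
  reg <- toy_registry(c(T1 = random_seq(80, 3), T2 = random_seq(80, 4)))
  cat0 <- make_variant_catalog(5, reg, n_path_per_isotype = c(12, 7),
                               n_benign_per_isotype = c(20, 9))
  d <- withr::local_tempdir()
  v <- cat0$variants
  for (l in c("pathogenic", "gnomad")) {
    sub <- v[v$label == l, ]
    writeLines(c("isotype,protein_change",
                 paste(sub$isotype,
                       format_protein_change(sub$wt_aa, sub$position, sub$mut_aa),
                       sep = ",")),
               file.path(d, paste0(l, ".csv")))
  }
  loaded <- rbind(load_variant_table(file.path(d, "pathogenic.csv"), "pathogenic", reg),
                  load_variant_table(file.path(d, "gnomad.csv"), "gnomad", reg))
  dd <- deduplicate_overlaps(variant_catalog(loaded, reg))
  oracle <- sapply(c("pathogenic", "gnomad"), function(l)
    table(sub("^([^,]+),.*$", "\\1",
              readLines(file.path(d, paste0(l, ".csv")))[-1])))
  got <- table(dd$variants$isotype, dd$variants$label)
  expect_equal(unname(got[, "pathogenic"]), unname(oracle[, "pathogenic"]))
  expect_equal(unname(got[, "gnomad"]), unname(oracle[, "gnomad"]))
})

test_that("phenotype grouping follows the published classification", {
  reg <- isotype_registry()
  expect_equal(phenotype_group("TUBA1A", reg), "neurodevelopmental")
  expect_equal(phenotype_group("TUBß8", reg), "other")
  expect_error(phenotype_group("TUBA1B", reg), "not groupable")
  expect_error(phenotype_group("TUBA3D", reg), "not groupable")
})
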