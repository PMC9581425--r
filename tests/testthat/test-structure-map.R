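write_toy <- function(toy, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, paste0(toy$structure_id, ".pdb"))
  writeLines(toy$pdb, p)
  p
}

test_that("toy PDB text parses back with chains, ligand and resolution", {
  toy <- make_toy_structure(1)
  st <- parse_structure(write_toy(toy))
  expect_s3_class(st, "structure_record")
  expect_setequal(names(st$chains), c("A", "B"))
  expect_equal(nrow(st$chains$A), 60)
  expect_equal(st$resolution, 2.5)
  expect_true(any(grepl("^GTP", names(st$ligands))))
  expect_equal(paste(st$chains$A$resid1, collapse = ""), toy$sequence)
  # chain residue order is monotone in author numbering
  expect_true(all(diff(st$chains$A$resno) > 0))
  expect_error(parse_structure(tempfile(fileext = ".pdb")), "no such file")
})

test_that("REMARK 350 biological-assembly transforms expand chain copies", {
  d <- withr::local_tempdir()
  p <- file.path(d, "asm.pdb")
  writeLines(c(
    "REMARK 350 BIOMOLECULE: 1",
    "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 350   BIOMT1   2  1.000000  0.000000  0.000000       20.00000",
    "REMARK 350   BIOMT2   2  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        0.00000",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), p)
  st <- parse_structure(p)
  expect_setequal(names(st$chains), c("A", "A.1"))
  a1 <- st$atoms[st$atoms$chain == "A.1", ]
  expect_equal(a1$x, c(20, 23.8))
  # assembly expansion can be disabled
  st0 <- parse_structure(p, apply_assembly = FALSE)
  expect_setequal(names(st0$chains), "A")
})

test_that("chain retention needs 70% identity over at least 50 aligned residues", {
  iso <- random_seq(100, 61)
  st_ident <- chain_only_record(list(A = iso))
  aln <- align_chain(iso, st_ident, "A")
  expect_equal(aln$percent_identity, 100)
  expect_equal(aln$aligned_length, 100)

  # 31 substitutions out of 100 -> 69% identity -> rejected
  mutate_at <- function(s, pos) {
    sc <- strsplit(s, "")[[1]]
    sc[pos] <- vapply(sc[pos], function(a) setdiff(tubulinvep:::AA1, a)[1], "")
    paste(sc, collapse = "")
  }
  set.seed(62)
  st_69 <- chain_only_record(list(A = mutate_at(iso, sample(100, 31))))
  expect_null(align_chain(iso, st_69, "A"))
  st_70 <- chain_only_record(list(A = mutate_at(iso, sample(100, 30))))
  expect_false(is.null(align_chain(iso, st_70, "A")))

  # an identical 49-mer fails the length floor
  iso49 <- random_seq(49, 63)
  expect_null(align_chain(iso49, chain_only_record(list(A = iso49)), "A"))
})

test_that("the triplet rule maps only positions with both neighbours identical in the structure", {
  iso <- random_seq(80, 64)
  sc <- strsplit(iso, "")[[1]]
  sc[40] <- setdiff(tubulinvep:::AA1, sc[40])[1]  # structure differs at 40
  st <- chain_only_record(list(A = paste(sc, collapse = "")))
  aln <- align_chain(iso, st, "A")

  expect_equal(map_position(aln, 20), 20)       # clean triplet
  expect_true(is.na(map_position(aln, 40)))     # centre mismatch
  expect_true(is.na(map_position(aln, 39)))     # neighbour mismatch
  expect_true(is.na(map_position(aln, 41)))
  expect_equal(map_position(aln, 42), 42)
  expect_true(is.na(map_position(aln, 1)))      # termini lack two neighbours
  expect_true(is.na(map_position(aln, 80)))
})

test_that("ligand contacts honour the cutoff and match the planted pocket", {
  toy <- make_toy_structure(2)
  st <- parse_structure(write_toy(toy))
  g <- ligand_contact_set(st, cutoff = 5)
  expect_equal(g$chain, "A")
  expect_equal(g$resno, 10)
  # a tiny cutoff finds nothing (all-pairs distances exceed it)
  expect_equal(nrow(ligand_contact_set(st, cutoff = 0.1)), 0)
  # absent ligand component codes: empty set
  expect_equal(nrow(ligand_contact_set(st, ligand_codes = "ATP")), 0)
})

test_that("interface contacts equal a brute-force all-pairs computation", {
  toy <- make_toy_structure(3)
  st <- parse_structure(write_toy(toy))
  got <- interface_contact_set(st, "A", "B", 5)
  expect_equal(sort(paste(got$chain, got$resno)),
               contact_oracle(st, "A", "B", 5))
  expect_equal(got$resno, 28:33)  # the planted patch

  rev <- interface_contact_set(st, "B", "A", 5)
  expect_equal(sort(paste(rev$chain, rev$resno)),
               contact_oracle(st, "B", "A", 5))
  expect_equal(nrow(interface_contact_set(st, "A", "B", 0.5)), 0)
  expect_error(interface_contact_set(st, "A", "A", 5), "disjoint")

  # random small instances against the oracle
  set.seed(65)
  for (rep in 1:5) {
    at <- data.frame(chain = rep(c("A", "B"), each = 20),
                     resno = rep(1:10, 4), resid = "ALA", resid1 = "A",
                     atom = "CA", element = "C",
                     x = runif(40, 0, 15), y = runif(40, 0, 15), z = runif(40, 0, 15),
                     het = FALSE, comp = "ALA", stringsAsFactors = FALSE)
    st_r <- structure(list(structure_id = "rnd", resolution = NA_real_,
                           atoms = at,
                           chains = lapply(split(at, at$chain), function(a)
                             unique(a[, c("resno", "resid1")])),
                           ligands = list()),
                      class = "structure_record")
    got_r <- interface_contact_set(st_r, "A", "B", 4)
    expect_equal(sort(paste(got_r$chain, got_r$resno)),
                 contact_oracle(st_r, "A", "B", 4))
  }
})

test_that("solvent accessibility: occlusion is monotone, buried residues hit zero, sampling converges", {
  # an isolated atom has the full expanded-sphere area
  one <- atom_sasa(matrix(0, 1, 3), "C")
  expect_equal(one, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)

  # adding atoms never increases another atom's SASA
  xyz <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  two <- atom_sasa(xyz, c("C", "C"))
  expect_lt(two[1], one)
  xyz3 <- rbind(xyz, c(-3, 0, 0))
  three <- atom_sasa(xyz3, c("C", "C", "C"))
  expect_lte(three[1], two[1])

  # default sampling density is within 2% of a 4x denser computation
  set.seed(66)
  cloud <- matrix(rnorm(30 * 3, sd = 4), 30, 3)
  el <- sample(c("C", "N", "O", "S"), 30, replace = TRUE)
  s960 <- atom_sasa(cloud, el, n_points = 960)
  s3840 <- atom_sasa(cloud, el, n_points = 3840)
  expect_lt(max(abs(s960 - s3840)) / max(s3840), 0.02)

  # a residue enclosed in a synthetic shell has rSASA 0; cage residues in the
  # toy structure are exactly that
  toy <- make_toy_structure(4)
  st <- parse_structure(write_toy(toy))
  rs <- relative_sasa(st, "A")
  expect_equal(unname(rs[as.character(44:46)]), c(0, 0, 0))
  expect_true(all(rs[as.character(c(2:8, 12:26))] > 0.25))

  # unknown elements fall back to the default radius with a warning
  expect_warning(atom_sasa(matrix(0, 1, 3), "ZZ"), "unknown element")
})

test_that("classification hierarchy resolves every flag combination in order", {
  combos <- expand.grid(gtp = c(TRUE, FALSE), intra = c(TRUE, FALSE),
                        map = c(TRUE, FALSE), inter = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    ev <- list(mapped = TRUE, gtp_contact = combos$gtp[i],
               intradimer = combos$intra[i], map_interface = combos$map[i],
               interdimer = combos$inter[i], rsasa = 0.5)
    expected <- if (combos$gtp[i]) "GTP_BINDING"
      else if (combos$intra[i]) "INTRADIMER"
      else if (combos$map[i]) "MAP_INTERFACE"
      else if (combos$inter[i]) "INTERDIMER"
      else "SURFACE"
    expect_equal(classify_position(ev), expected)
  }
  no_flags <- function(rsasa) list(mapped = TRUE, gtp_contact = FALSE,
                                   intradimer = FALSE, map_interface = FALSE,
                                   interdimer = FALSE, rsasa = rsasa)
  expect_equal(classify_position(no_flags(0.30)), "SURFACE")
  expect_equal(classify_position(no_flags(0.25)), "INTERIOR")  # strict >
  expect_equal(classify_position(list(mapped = FALSE)), "OUTSIDE_STRUCTURE")
  expect_error(classify_position(no_flags(NA_real_)), "incomplete evidence")
})

test_that("full annotation recovers planted classes and honours resolution precedence", {
  toy <- make_toy_structure(5)
  d <- withr::local_tempdir()
  writeLines(toy$pdb, file.path(d, "toy1.pdb"))
  st <- parse_structure(file.path(d, "toy1.pdb"))
  reg <- toy_registry(c(TOY1 = toy$sequence))
  cat1 <- make_variant_catalog(6, reg, 30, 30, truth = toy$truth)
  ann <- annotate_catalog(cat1, list(st), list(toy$model_role))
  expect_equal(ann$location_class, cat1$variants$truth_class)
  expect_true(all(!is.na(ann$location_class)))

  # same position in two structures with conflicting burial: the
  # higher-resolution structure supplies the rSASA
  toy_open <- make_toy_structure(5, with_cage = FALSE, with_ligand = FALSE,
                                 structure_id = "toy2", resolution = 1.8)
  writeLines(toy_open$pdb, file.path(d, "toy2.pdb"))
  st_open <- parse_structure(file.path(d, "toy2.pdb"))
  v45 <- make_variants_df(reg, "TOY1", 45)
  cat45 <- variant_catalog(rbind(v45, make_variants_df(reg, "TOY1", 20,
                                                       label = "gnomad")), reg)
  # open structure is sharper (1.8 vs 2.5): position 45 reads as SURFACE
  ann_hi <- annotate_catalog(cat45, list(st, st_open), list(toy$model_role))
  expect_equal(ann_hi$location_class[1], "SURFACE")
  # with the caged structure sharper instead, the same position is INTERIOR
  toy_open_lo <- make_toy_structure(5, with_cage = FALSE, with_ligand = FALSE,
                                    structure_id = "toy2", resolution = 3.9)
  writeLines(toy_open_lo$pdb, file.path(d, "toy2.pdb"))
  st_open_lo <- parse_structure(file.path(d, "toy2.pdb"))
  ann_lo <- annotate_catalog(cat45, list(st, st_open_lo), list(toy$model_role))
  expect_equal(ann_lo$location_class[1], "INTERIOR")

  # an isotype with no retained structure gets OUTSIDE_STRUCTURE with a warning
  reg2 <- toy_registry(c(TOY1 = toy$sequence, LONE1 = random_seq(120, 67)))
  catx <- variant_catalog(rbind(make_variants_df(reg2, "LONE1", c(10, 11)),
                                make_variants_df(reg2, "LONE1", 30,
                                                 label = "gnomad")), reg2)
  expect_warning(annx <- annotate_catalog(catx, list(st), list(toy$model_role)),
                 "no structure retained")
  expect_true(all(annx$location_class == "OUTSIDE_STRUCTURE"))
})
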