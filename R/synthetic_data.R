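# Seeded synthetic-data generators with planted ground truth: toy
# structures, variant catalogs, VEP score matrices and ddG tables.
# Noise models are simple normals; the goal is controlled recovery of
# planted truth, not realism.

# Run expr with a private RNG stream, restoring the caller's stream after.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_aa_sequence <- function(n, exclude_pos = integer(), fixed = character()) {
  s <- sample(AA1, n, replace = TRUE)
  if (length(fixed)) s[as.integer(names(fixed))] <- fixed
  paste(s, collapse = "")
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

pdb_atom_line <- function(record, serial, name, resname, chain, resno, xyz, element) {
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_f, " ", resname, chain, resno, " ",
          xyz[1], xyz[2], xyz[3], 1.0, 0.0, element)
}

# Fixed internal geometry of the toy assembly. All inter-atomic distances
# are seed-independent: the seed only applies a rigid rotation+translation,
# so planted classes hold for every seed.
toy_geometry <- function(n_res, with_ligand, with_cage,
                         patch = 28:33, pocket_res = 10, cage_center_res = 45) {
  stopifnot(n_res >= 10)
  spacing <- 3.8
  residue_atoms <- function(i, y0, face) {
    t <- (i - 1) * spacing
    rbind(N  = c(t - 0.6, y0 - face * 0.4, 0.0),
          CA = c(t, y0, 0.0),
          C  = c(t + 0.6, y0 - face * 0.4, 0.0),
          O  = c(t + 0.6, y0 - face * 0.4, 1.2),
          CB = c(t, y0 + face * 1.5, 0.8))
  }
  atoms <- list()
  add <- function(record, name, resname, chain, resno, xyz, element) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      record = record, name = name, resname = resname, chain = chain,
      resno = resno, x = xyz[1], y = xyz[2], z = xyz[3], element = element,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res)) {
    xyz <- residue_atoms(i, 0, -1)                       # chain A, CB toward B
    for (nm in rownames(xyz))
      add("ATOM", nm, NA, "A", i, xyz[nm, ], substr(nm, 1, 1))
  }
  for (i in seq_len(n_res)) {
    y0 <- if (i %in% patch) -6.8 else -12.0              # chain B approaches at the patch
    xyz <- residue_atoms(i, y0, +1)
    for (nm in rownames(xyz))
      add("HETATM0", nm, NA, "B", i, xyz[nm, ], substr(nm, 1, 1))  # placeholder record
  }
  if (with_ligand) {
    t <- (pocket_res - 1) * spacing
    lig <- rbind(c(t, -1.5, 4.8), c(t, -1.5, 5.6), c(t, -1.1, 5.2), c(t, -1.9, 5.2))
    el <- c("P", "O", "C", "N")
    for (k in 1:4)
      add("HETATM", paste0(el[k], k), "GTP", "L", 1, lig[k, ], el[k])
  }
  if (with_cage) {
    ctr <- c((cage_center_res - 1) * spacing, 0, 0.5)
    shell <- rbind(sphere_points(120) * 6.5, sphere_points(40) * 4.5)
    shell <- sweep(shell, 2, ctr, "+")
    for (k in seq_len(nrow(shell)))
      add("HETATM", paste0("C", k %% 100), "CAG", "X", k, shell[k, ], "C")
  }
  at <- do.call(rbind, atoms)
  at$record[at$record == "HETATM0"] <- "ATOM"
  at
}

#' Generate a toy two-chain structure with planted location classes
#'
#' Builds a rigid toy assembly: two extended pseudo-chains ("A", the
#' annotated chain, and "B", a partner) that touch over a planted interface
#' patch; an optional 4-atom GTP ligand 3.6 A from a pocket residue; and an
#' occluding atom cage that buries a short core segment. The seed applies
#' only a rigid rotation and translation, so all planted contacts, burial
#' and classes are identical for every seed. Chain A's sequence doubles as
#' the isotype sequence; chain B carries an unrelated sequence so only
#' chain A is ever retained by alignment.
#'
#' @param seed integer seed.
#' @param n_res_per_chain residues per chain (>= 60 so alignments meet the
#'   50-residue retention floor).
#' @param with_ligand place the GTP ligand (else no GTP-binding truth).
#' @param with_cage place the burial cage (else no interior truth).
#' @param interface_role role the A/B interface plays in `model_roles`:
#'   `"lattice_model"` (interdimer truth), `"intradimer_model"` or
#'   `"map_model"`.
#' @param structure_id,resolution metadata written into the PDB text.
#' @return list with `pdb` (character vector of PDB lines), `sequence`
#'   (chain A / isotype sequence), `truth` (data frame `position`,
#'   `class`; buffer positions adjacent to planted features are omitted),
#'   `model_role` (a [model_role()] entry), `structure_id`.
#' @export
make_toy_structure <- function(seed, n_res_per_chain = 60, with_ligand = TRUE,
                               with_cage = TRUE,
                               interface_role = c("lattice_model",
                                                  "intradimer_model", "map_model"),
                               structure_id = "toy1", resolution = 2.5) {
  interface_role <- match.arg(interface_role)
  stopifnot(n_res_per_chain >= 10)
  patch <- 28:33; pocket <- 10; cage_res <- 45
  with_rng(seed, {
    seq_a <- random_aa_sequence(n_res_per_chain)
    seq_b <- random_aa_sequence(n_res_per_chain)
    at <- toy_geometry(n_res_per_chain, with_ligand, with_cage,
                       patch = patch, pocket_res = pocket,
                       cage_center_res = cage_res)
    rot <- random_rotation()
    shift <- runif(3, -5, 5)
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rot)
    at$x <- xyz[, 1] + shift[1]
    at$y <- xyz[, 2] + shift[2]
    at$z <- xyz[, 3] + shift[3]
  })
  letters_ab <- c(strsplit(seq_a, "")[[1]], strsplit(seq_b, "")[[1]])
  names(letters_ab) <- c(paste("A", seq_len(n_res_per_chain)),
                         paste("B", seq_len(n_res_per_chain)))
  poly <- at$record == "ATOM"
  at$resname[poly] <- bio3d::aa123(unname(letters_ab[paste(at$chain[poly], at$resno[poly])]))
  lines <- c(
    sprintf("HEADER    SYNTHETIC TOY TUBULIN-LIKE ASSEMBLY     %s", toupper(structure_id)),
    sprintf("REMARK   2 RESOLUTION.  %6.2f ANGSTROMS.", resolution),
    vapply(seq_len(nrow(at)), function(k)
      pdb_atom_line(sub("0$", "", at$record[k]), k, at$name[k], at$resname[k],
                    at$chain[k], at$resno[k],
                    c(at$x[k], at$y[k], at$z[k]), at$element[k]),
      character(1)),
    "END")

  iface_class <- c(lattice_model = "INTERDIMER",
                   intradimer_model = "INTRADIMER",
                   map_model = "MAP_INTERFACE")[[interface_role]]
  truth <- data.frame(position = seq_len(n_res_per_chain),
                      class = "SURFACE", stringsAsFactors = FALSE)
  truth$class[c(1, n_res_per_chain)] <- "OUTSIDE_STRUCTURE"   # no triplet at termini
  truth$class[patch] <- iface_class
  if (with_ligand) truth$class[pocket] <- "GTP_BINDING"
  if (with_cage) {
    truth$class[44:46] <- "INTERIOR"
    truth <- truth[!truth$position %in% c(41:43, 47:49), , drop = FALSE]  # burial buffer
  }
  list(pdb = lines, sequence = seq_a, truth = truth,
       model_role = model_role(structure_id, interface_role,
                               group_a = "A", group_b = "B"),
       structure_id = structure_id)
}

#' Generate a synthetic variant catalog with optional planted enrichment
#'
#' Samples distinct substitutions per isotype; pathogenic and gnomAD sets
#' are disjoint by construction. Without `class_enrichment`, counts default
#' to the registry's reported per-isotype totals, mirroring the published
#' survey counts. With `class_enrichment` (and `truth` giving each
#' position's planted class), pathogenic variants are drawn with sampling
#' odds multiplied per class, planting a location enrichment of known
#' strength.
#'
#' @param seed integer seed.
#' @param registry an [isotype_registry()] (or compatible data frame).
#' @param n_path_per_isotype,n_benign_per_isotype counts; default to the
#'   registry's `n_pathogenic` / `n_gnomad` columns.
#' @param class_enrichment named numeric vector of pathogenic sampling odds
#'   per location class (unnamed classes get odds 1).
#' @param truth data frame `position`, `class` (as from
#'   [make_toy_structure()]); required with `class_enrichment`, and
#'   restricts variants to truth positions.
#' @return a [variant_catalog()]; variant rows carry a `truth_class`
#'   column when `truth` was supplied.
#' @export
make_variant_catalog <- function(seed, registry,
                                 n_path_per_isotype = NULL,
                                 n_benign_per_isotype = NULL,
                                 class_enrichment = NULL, truth = NULL) {
  if (!is.null(class_enrichment) && is.null(truth))
    stop("class_enrichment requires truth positions")
  n_iso <- nrow(registry)
  n_path <- rep_len(n_path_per_isotype %||% registry$n_pathogenic, n_iso)
  n_ben <- rep_len(n_benign_per_isotype %||% registry$n_gnomad, n_iso)
  with_rng(seed, {
    rows <- lapply(seq_len(n_iso), function(j) {
      seqc <- strsplit(registry$sequence[j], "")[[1]]
      pos_pool <- if (is.null(truth)) seq_along(seqc) else truth$position
      subs <- expand.grid(position = pos_pool, mut_aa = AA1,
                          stringsAsFactors = FALSE)
      subs$wt_aa <- seqc[subs$position]
      subs <- subs[subs$wt_aa != subs$mut_aa, , drop = FALSE]
      need <- n_path[j] + n_ben[j]
      if (need == 0) return(NULL)
      if (need > nrow(subs))
        stop("requested counts exceed available substitutions for ",
             registry$gene_symbol[j])
      w <- rep(1, nrow(subs))
      if (!is.null(class_enrichment)) {
        cls <- truth$class[match(subs$position, truth$position)]
        odds <- class_enrichment[cls]
        odds[is.na(odds)] <- 1
        w <- as.numeric(odds)
      }
      i_path <- if (n_path[j] > 0) sample(nrow(subs), n_path[j], prob = w) else integer()
      rest <- setdiff(seq_len(nrow(subs)), i_path)
      i_ben <- if (n_ben[j] > 0) sample(rest, n_ben[j]) else integer()
      sel <- c(i_path, i_ben)
      df <- subs[sel, , drop = FALSE]
      df$isotype <- registry$gene_symbol[j]
      df$label <- rep(c("pathogenic", "gnomad"), c(n_path[j], n_ben[j]))
      df$source <- "synthetic"
      if (!is.null(truth))
        df$truth_class <- truth$class[match(df$position, truth$position)]
      df
    })
    variants <- do.call(rbind, rows)
  })
  rownames(variants) <- NULL
  variant_catalog(variants[, c("isotype", "position", "wt_aa", "mut_aa",
                               "label", "source",
                               intersect("truth_class", names(variants))),
                           drop = FALSE],
                  registry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regenerate the packaged synthetic registry sequences
#'
#' The packaged FASTA of isotype sequences is synthetic: deterministic
#' random sequences of realistic tubulin lengths (about 450 residues),
#' one per isotype in the packaged metadata table. They stand in for the
#' canonical sequences so that every position-validated workflow can run
#' self-contained; supply a real FASTA to [isotype_registry()] for real
#' analyses.
#'
#' @param path output FASTA path.
#' @param seed integer seed (default matches the packaged file).
#' @param metadata metadata TSV (defaults to the packaged table).
#' @return invisibly, the named character vector of sequences.
#' @export
make_synthetic_registry_fasta <- function(path, seed = 101,
                                          metadata = system.file(
                                            "extdata", "tubulin_isotypes.tsv",
                                            package = "tubulinvep")) {
  meta <- read.delim(metadata, stringsAsFactors = FALSE)
  len <- ifelse(meta$family == "beta" & meta$gene_symbol != "TUBB1", 444L, 451L)
  seqs <- with_rng(seed, {
    setNames(vapply(len, random_aa_sequence, character(1)), meta$gene_symbol)
  })
  writeLines(c(rbind(paste0(">", names(seqs), " synthetic stand-in sequence"),
                     seqs)), path)
  invisible(seqs)
}

#' Generate a VEP score matrix with planted per-predictor effect sizes
#'
#' Benign scores are N(0,1) and pathogenic scores N(d,1) per predictor, so
#' the expected AUC is Phi(d/sqrt(2)). Inverse-flagged predictors have
#' their columns negated (and are flagged accordingly in the returned
#' table); cells are masked missing at the given rate.
#'
#' @param seed integer seed.
#' @param n_path,n_benign row counts (ignored when `catalog` is given).
#' @param predictors data frame with columns `name`, `d`, `inverse`
#'   (logical), `missing_rate`.
#' @param catalog optional [variant_catalog()]: rows then follow the
#'   catalog's variants (keys `ISOTYPE:CHANGE`) with pathogenic rows
#'   shifted.
#' @return list with `table` (a [vep_table()]), `labels` (character
#'   vector aligned to rows) and `expected_auc` (named per predictor).
#' @export
make_score_matrix <- function(seed, n_path = 100, n_benign = 100,
                              predictors = data.frame(
                                name = c("alpha_vep", "beta_vep"),
                                d = c(1, 0.5),
                                inverse = c(FALSE, TRUE),
                                missing_rate = c(0, 0.05)),
                              catalog = NULL) {
  if (!is.null(catalog)) {
    v <- catalog$variants
    labels <- v$label
    keys <- paste(v$isotype, format_protein_change(v$wt_aa, v$position, v$mut_aa),
                  sep = ":")
  } else {
    labels <- rep(c("pathogenic", "gnomad"), c(n_path, n_benign))
    keys <- sprintf("SYN:p%d", seq_along(labels))
  }
  n <- length(labels)
  with_rng(seed, {
    m <- matrix(NA_real_, n, nrow(predictors),
                dimnames = list(keys, predictors$name))
    for (k in seq_len(nrow(predictors))) {
      s <- rnorm(n) + ifelse(labels == "pathogenic", predictors$d[k], 0)
      if (predictors$inverse[k]) s <- -s
      if (predictors$missing_rate[k] > 0)
        s[runif(n) < predictors$missing_rate[k]] <- NA
      m[, k] <- s
    }
  })
  ori <- setNames(ifelse(predictors$inverse, "inverse", "direct"), predictors$name)
  list(table = vep_table(m, ori[ori == "inverse"]),
       labels = labels,
       expected_auc = setNames(stats::pnorm(predictors$d / sqrt(2)), predictors$name))
}

#' Generate a synthetic ddG table with a controlled group shift
#'
#' gnomAD variants draw ddG_fold from N(0.5, 1.2) and pathogenic variants
#' from N(0.5 + shift, 1.2); ddG_full adds correlated N(0, 0.3) noise to
#' ddG_fold.
#'
#' @param seed integer seed.
#' @param catalog a [variant_catalog()].
#' @param shift_kcal planted pathogenic shift in kcal/mol.
#' @return data frame `isotype, protein_change, ddg_fold, ddg_full`.
#' @export
make_ddg_table <- function(seed, catalog, shift_kcal = 1) {
  v <- catalog$variants
  if (!nrow(v)) stop("catalog is empty")
  with_rng(seed, {
    mu <- 0.5 + ifelse(v$label == "pathogenic", shift_kcal, 0)
    fold <- rnorm(nrow(v), mu, 1.2)
    full <- fold + rnorm(nrow(v), 0, 0.3)
  })
  data.frame(isotype = v$isotype,
             protein_change = format_protein_change(v$wt_aa, v$position, v$mut_aa),
             ddg_fold = round(fold, 4), ddg_full = round(full, 4),
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic input bundle for the pipeline
#'
#' Generates two toy isotypes (one linked to a neurodevelopmental
#' phenotype, one to another phenotype), one toy structure per isotype, a
#' variant catalog with a planted interdimer enrichment, a VEP score
#' matrix with planted effect sizes, and a ddG table, and writes them
#' (plus the ground truth and a ready-to-run config) to `dir`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving every generator.
#' @param n_path,n_benign variants per isotype and label.
#' @param interdimer_odds planted pathogenic sampling odds at the
#'   interface patch.
#' @param d effect size of the strongest planted predictor.
#' @param shift_kcal planted ddG shift.
#' @return invisibly, the path to the written config file.
#' @export
simulate_bundle <- function(dir, seed, n_path = 100, n_benign = 100,
                            interdimer_odds = 5, d = 1, shift_kcal = 1) {
  dir.create(file.path(dir, "structures"), recursive = TRUE, showWarnings = FALSE)
  toys <- list(
    TOYA1 = make_toy_structure(seed, structure_id = "toy_a", resolution = 2.2),
    TOYB8 = make_toy_structure(seed + 1, structure_id = "toy_b", resolution = 3.1))
  registry <- data.frame(
    gene_symbol = names(toys), family = c("alpha", "beta"),
    n_pathogenic = n_path, n_gnomad = n_benign, mcm = c(5.0, 1.8),
    phenotype_class = c("neurodevelopmental", "other"),
    sequence = vapply(toys, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  class(registry) <- c("isotype_registry", class(registry))

  for (nm in names(toys))
    writeLines(toys[[nm]]$pdb,
               file.path(dir, "structures", paste0(toys[[nm]]$structure_id, ".pdb")))
  # each isotype maps only to its own structure (unrelated sequences), so a
  # shared planted-truth table per isotype is recorded alongside
  catalog <- do.call(rbind, lapply(names(toys), function(nm) {
    cat1 <- make_variant_catalog(
      seed + match(nm, names(toys)),
      registry[registry$gene_symbol == nm, , drop = FALSE],
      n_path_per_isotype = n_path, n_benign_per_isotype = n_benign,
      class_enrichment = c(INTERDIMER = interdimer_odds),
      truth = toys[[nm]]$truth)
    cat1$variants
  }))
  full_catalog <- variant_catalog(catalog, registry)

  v <- full_catalog$variants
  write_df <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = ",", quote = FALSE, row.names = FALSE)
    p
  }
  write_df(data.frame(isotype = v$isotype,
                      protein_change = format_protein_change(v$wt_aa, v$position, v$mut_aa),
                      label = v$label, source = v$source), "catalog.csv")
  write.table(registry[, setdiff(names(registry), "sequence")],
              file.path(dir, "registry.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(rbind(paste0(">", registry$gene_symbol), registry$sequence)),
             file.path(dir, "registry.fasta"))

  predictors <- data.frame(
    name = c("strong_direct", "strong_inverse", "weak_direct", "null_vep"),
    d = c(d, d, d / 2, 0),
    inverse = c(FALSE, TRUE, FALSE, FALSE),
    missing_rate = c(0, 0.05, 0.02, 0))
  sm <- make_score_matrix(seed + 10, predictors = predictors, catalog = full_catalog)
  sc <- data.frame(isotype = v$isotype,
                   protein_change = format_protein_change(v$wt_aa, v$position, v$mut_aa),
                   sm$table$scores, check.names = FALSE)
  write_df(sc, "scores.csv")
  write_df(make_ddg_table(seed + 20, full_catalog, shift_kcal), "ddg.csv")

  truth <- list(seed = seed,
                planted = lapply(toys, function(t)
                  as.list(setNames(t$truth$class, t$truth$position))),
                interdimer_odds = interdimer_odds,
                expected_auc = as.list(sm$expected_auc),
                ddg_shift = shift_kcal)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)

  config <- list(
    registry_metadata = "registry.tsv",
    registry_fasta = "registry.fasta",
    catalog_csv = "catalog.csv",
    scores_csv = "scores.csv",
    ddg_csv = "ddg.csv",
    structures_dir = "structures",
    inverse_predictors = predictors$name[predictors$inverse],
    model_roles = lapply(toys, `[[`, "model_role"),
    contact_cutoff = 5.0,
    rsasa_threshold = 0.25,
    min_pathogenic_enrich = 5,
    min_pathogenic_auc = 10,
    seed = seed)
  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg)
  invisible(cfg)
}
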