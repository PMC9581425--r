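# Mapping variant positions onto tubulin structures: parsing, chain
# alignment, triplet-rule position mapping, contact detection and the
# hierarchical structural-location classification.

LOCATION_CLASSES <- c("GTP_BINDING", "INTRADIMER", "MAP_INTERFACE",
                      "INTERDIMER", "INTERIOR", "SURFACE", "OUTSIDE_STRUCTURE")

GTP_ANALOGUE_CODES <- c("GTP", "GDP", "GNP", "GSP", "GCP", "G2P")

#' Parse a PDB or mmCIF structure file
#'
#' Reads coordinates with bio3d, captures the resolution when present and,
#' for PDB files carrying REMARK 350 records, expands the first biological
#' assembly (additional transform copies get chain ids suffixed `.k`).
#' Water is dropped; other het groups are kept as ligands.
#'
#' @param path file path (`.pdb` or `.cif`).
#' @param structure_id identifier; defaults to the file base name.
#' @param apply_assembly expand biological assembly 1 when transforms are
#'   present (PDB only).
#' @return object of class `structure_record`: list with `structure_id`,
#'   `resolution`, `atoms` (data frame: `chain, resno, resid, resid1,
#'   atom, element, x, y, z, het, comp`), `chains` (per-chain residue
#'   tables) and `ligands`.
#' @export
parse_structure <- function(path, structure_id = NULL, apply_assembly = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("unreadable structure file '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$resid != "HOH", , drop = FALSE]
  if (!nrow(a)) stop("no atoms in structure: ", path)
  atoms <- data.frame(
    chain = as.character(a$chain), resno = a$resno,
    resid = a$resid,
    resid1 = suppressWarnings(bio3d::aa321(a$resid)),
    atom = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "", substr(trimws(a$elety), 1, 1), a$elesy),
    x = a$x, y = a$y, z = a$z,
    het = a$type != "ATOM",
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$comp <- atoms$resid

  resolution <- NA_real_
  if (!is_cif) {
    hdr <- readLines(path, warn = FALSE)
    rl <- grep("^REMARK   2 RESOLUTION", hdr, value = TRUE)
    if (length(rl)) {
      m <- regmatches(rl[1], regexec("([0-9]+\\.?[0-9]*) *ANGSTROM", rl[1]))[[1]]
      if (length(m) == 2) resolution <- as.numeric(m[2])
    }
    if (apply_assembly) {
      tr <- parse_biomt(hdr)
      if (!is.null(tr)) atoms <- apply_assembly_transforms(atoms, tr)
    }
  }

  poly <- atoms[!atoms$het & !is.na(atoms$resid1) & atoms$resid1 != "X", , drop = FALSE]
  if (!nrow(poly)) stop("no polymer chains in structure: ", path)
  chains <- lapply(split(poly, poly$chain), function(ch) {
    res <- unique(ch[, c("resno", "resid1")])
    res[order(res$resno), , drop = FALSE]
  })
  lig <- atoms[atoms$het, , drop = FALSE]
  structure(list(
    structure_id = if (is.null(structure_id))
      sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
      else structure_id,
    resolution = resolution,
    atoms = atoms,
    chains = chains,
    ligands = if (nrow(lig)) split(lig, paste(lig$comp, lig$chain, lig$resno)) else list()
  ), class = "structure_record")
}

# Parse REMARK 350 of biomolecule 1 into a list of
# list(chains=..., mat=3x3, vec=3) transforms; NULL when absent.
parse_biomt <- function(lines) {
  r350 <- grep("^REMARK 350", lines, value = TRUE)
  if (!length(r350)) return(NULL)
  bm <- grep("BIOMOLECULE:", r350)
  if (!length(bm)) return(NULL)
  end <- if (length(bm) > 1) bm[2] - 1 else length(r350)
  block <- r350[bm[1]:end]
  chains <- character()
  transforms <- list()
  cur <- NULL
  for (ln in block) {
    if (grepl("APPLY THE FOLLOWING TO CHAINS:|AND CHAINS:", ln)) {
      cs <- sub(".*CHAINS:", "", ln)
      chains <- c(chains, trimws(strsplit(cs, ",")[[1]]))
    } else if (grepl("BIOMT[123]", ln)) {
      f <- strsplit(trimws(sub(".*BIOMT([123])", "\\1", ln)), "\\s+")[[1]]
      row <- as.numeric(f[1]); opno <- f[2]
      vals <- as.numeric(f[3:6])
      if (is.null(cur) || cur$op != opno) {
        if (!is.null(cur)) transforms[[length(transforms) + 1]] <- cur
        cur <- list(op = opno, mat = matrix(0, 3, 3), vec = numeric(3))
      }
      cur$mat[row, ] <- vals[1:3]
      cur$vec[row] <- vals[4]
    }
  }
  if (!is.null(cur)) transforms[[length(transforms) + 1]] <- cur
  if (!length(transforms)) return(NULL)
  lapply(transforms, function(t) { t$chains <- chains; t })
}

is_identity_transform <- function(t) {
  all(abs(t$mat - diag(3)) < 1e-6) && all(abs(t$vec) < 1e-6)
}

apply_assembly_transforms <- function(atoms, transforms) {
  out <- list()
  copy <- 0
  for (t in transforms) {
    sel <- atoms$chain %in% t$chains
    if (!any(sel)) next
    blk <- atoms[sel, , drop = FALSE]
    if (is_identity_transform(t)) {
      out[[length(out) + 1]] <- blk
    } else {
      copy <- copy + 1
      xyz <- as.matrix(blk[, c("x", "y", "z")]) %*% t(t$mat)
      blk$x <- xyz[, 1] + t$vec[1]
      blk$y <- xyz[, 2] + t$vec[2]
      blk$z <- xyz[, 3] + t$vec[3]
      blk$chain <- paste0(blk$chain, ".", copy)
      out[[length(out) + 1]] <- blk
    }
  }
  untouched <- atoms[!atoms$chain %in% unique(unlist(lapply(transforms, `[[`, "chains"))), ,
                     drop = FALSE]
  rbind(do.call(rbind, out), untouched)
}

chain_sequence <- function(structure, chain_id) {
  ch <- structure$chains[[chain_id]]
  if (is.null(ch)) stop("chain '", chain_id, "' not in structure")
  paste(ch$resid1, collapse = "")
}

#' Align an isotype sequence to a structure chain
#'
#' Global (Needleman-Wunsch, BLOSUM62) alignment of the isotype sequence to
#' the chain's observed residues. The alignment is retained only when the
#' percent identity over aligned (non-gap) columns is at least
#' `min_identity` and at least `min_aligned` columns align.
#'
#' @param isotype_seq isotype amino-acid sequence (1-letter string).
#' @param structure a `structure_record`.
#' @param chain_id chain identifier.
#' @param min_identity,min_aligned retention thresholds (70% / 50 residues).
#' @return `NULL` when the thresholds are not met; otherwise a
#'   `chain_alignment`: list with `pairs` (data frame `isotype_pos`,
#'   `chain_idx`, `resno`, `iso_aa`, `chain_aa`), `percent_identity`,
#'   `aligned_length`, `score`, `chain_id`, `structure_id`.
#' @export
align_chain <- function(isotype_seq, structure, chain_id,
                        min_identity = 70, min_aligned = 50) {
  cseq <- chain_sequence(structure, chain_id)
  if (!nchar(cseq)) return(NULL)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(isotype_seq), Biostrings::AAString(cseq),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ipos <- cumsum(p != "-")
  cpos <- cumsum(s != "-")
  both <- p != "-" & s != "-"
  aligned_length <- sum(both)
  if (aligned_length == 0) return(NULL)
  identity <- 100 * sum(p[both] == s[both]) / aligned_length
  if (identity < min_identity || aligned_length < min_aligned) return(NULL)
  ch <- structure$chains[[chain_id]]
  pairs <- data.frame(isotype_pos = ipos[both], chain_idx = cpos[both],
                      resno = ch$resno[cpos[both]],
                      iso_aa = p[both], chain_aa = s[both],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, percent_identity = identity,
                 aligned_length = aligned_length,
                 score = Biostrings::score(aln),
                 chain_id = chain_id, structure_id = structure$structure_id),
            class = "chain_alignment")
}

#' Map an isotype position onto a structure residue (triplet rule)
#'
#' A position maps only when it and both sequence neighbours align to
#' consecutive chain residues with identical amino acids — the structure
#' must literally show the isotype's local sequence. Terminal positions
#' (no two neighbours) are unmappable.
#'
#' @param alignment a `chain_alignment` from [align_chain()].
#' @param isotype_pos 1-based position on the isotype sequence.
#' @return the chain residue number (author numbering), or `NA` when the
#'   rule is not satisfied.
#' @export
map_position <- function(alignment, isotype_pos) {
  stopifnot(inherits(alignment, "chain_alignment"))
  pr <- alignment$pairs
  idx <- match(c(isotype_pos - 1, isotype_pos, isotype_pos + 1), pr$isotype_pos)
  if (anyNA(idx)) return(NA_integer_)
  trip <- pr[idx, ]
  if (any(trip$iso_aa != trip$chain_aa)) return(NA_integer_)
  if (!all(diff(trip$chain_idx) == 1)) return(NA_integer_)
  trip$resno[2]
}

# minimum pairwise distance test between two heavy-atom coordinate sets
atoms_within <- function(a_xyz, b_xyz, cutoff) {
  # returns logical per row of a_xyz: any b atom within cutoff
  if (!nrow(a_xyz) || !nrow(b_xyz)) return(rep(FALSE, nrow(a_xyz)))
  out <- rep(FALSE, nrow(a_xyz))
  c2 <- cutoff^2
  for (j in seq_len(nrow(b_xyz))) {
    d2 <- (a_xyz[, 1] - b_xyz[j, 1])^2 + (a_xyz[, 2] - b_xyz[j, 2])^2 +
      (a_xyz[, 3] - b_xyz[j, 3])^2
    out <- out | d2 <= c2
    if (all(out)) break
  }
  out
}

heavy_atoms <- function(structure) {
  at <- structure$atoms
  at[toupper(at$element) != "H", , drop = FALSE]
}

#' Residues contacting a ligand
#'
#' Polymer residues with at least one heavy atom within `cutoff` of any
#' heavy atom of a ligand whose component code is in `ligand_codes`.
#'
#' @param structure a `structure_record`.
#' @param ligand_codes component codes (default: GTP and common analogues).
#' @param cutoff contact distance in Angstrom.
#' @return data frame `chain`, `resno` of contacting residues.
#' @export
ligand_contact_set <- function(structure, ligand_codes = GTP_ANALOGUE_CODES,
                               cutoff = 5.0) {
  stopifnot(cutoff > 0)
  at <- heavy_atoms(structure)
  lig <- at[at$het & at$comp %in% ligand_codes, , drop = FALSE]
  poly <- at[!at$het, , drop = FALSE]
  if (!nrow(lig) || !nrow(poly))
    return(data.frame(chain = character(), resno = integer()))
  hit <- atoms_within(as.matrix(poly[, c("x", "y", "z")]),
                      as.matrix(lig[, c("x", "y", "z")]), cutoff)
  unique(poly[hit, c("chain", "resno")])
}

#' Residues of one chain group contacting another
#'
#' @param structure a `structure_record`.
#' @param group_a,group_b disjoint sets of chain ids; contacts are reported
#'   for `group_a` residues.
#' @param cutoff heavy-atom contact distance in Angstrom.
#' @return data frame `chain`, `resno` of `group_a` residues with at least
#'   one heavy atom within `cutoff` of any `group_b` heavy atom.
#' @export
interface_contact_set <- function(structure, group_a, group_b, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  if (length(intersect(group_a, group_b)))
    stop("chain groups must be disjoint")
  at <- heavy_atoms(structure)
  a <- at[!at$het & at$chain %in% group_a, , drop = FALSE]
  b <- at[at$chain %in% group_b, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    return(data.frame(chain = character(), resno = integer()))
  hit <- atoms_within(as.matrix(a[, c("x", "y", "z")]),
                      as.matrix(b[, c("x", "y", "z")]), cutoff)
  unique(a[hit, c("chain", "resno")])
}

#' Assign the structural-location class from assembled evidence
#'
#' The hierarchy is applied in fixed order: GTP binding, intradimer
#' interface, MAP interface, interdimer (microtubule lattice) contact; a
#' position matching none of these is SURFACE when rSASA is strictly
#' greater than the threshold, otherwise INTERIOR; positions never mapped
#' into any structure are OUTSIDE_STRUCTURE.
#'
#' @param evidence list with logical `mapped`, flags `gtp_contact`,
#'   `intradimer`, `map_interface`, `interdimer`, and numeric `rsasa`
#'   (may be `NA` when any flag is set).
#' @param rsasa_threshold surface cut (default 0.25, strict `>`).
#' @return one of `r paste(LOCATION_CLASSES, collapse=", ")`.
#' @export
classify_position <- function(evidence, rsasa_threshold = 0.25) {
  if (!isTRUE(evidence$mapped)) return("OUTSIDE_STRUCTURE")
  if (isTRUE(evidence$gtp_contact)) return("GTP_BINDING")
  if (isTRUE(evidence$intradimer)) return("INTRADIMER")
  if (isTRUE(evidence$map_interface)) return("MAP_INTERFACE")
  if (isTRUE(evidence$interdimer)) return("INTERDIMER")
  if (is.null(evidence$rsasa) || is.na(evidence$rsasa))
    stop("incomplete evidence: mapped position with no flags and no rSASA")
  if (evidence$rsasa > rsasa_threshold) "SURFACE" else "INTERIOR"
}

#' Model-role entry for interface assignment
#'
#' @param structure_id structure the roles apply to.
#' @param role `"intradimer_model"`, `"map_model"` or `"lattice_model"`.
#' @param group_a chains the variant may map to.
#' @param group_b partner chains defining the interface.
#' @return list usable in the `model_roles` argument of
#'   [annotate_catalog()].
#' @export
model_role <- function(structure_id, role = c("intradimer_model", "map_model",
                                              "lattice_model"),
                       group_a, group_b) {
  role <- match.arg(role)
  list(structure_id = structure_id, role = role,
       group_a = group_a, group_b = group_b)
}

role_flag <- c(intradimer_model = "intradimer",
               map_model = "map_interface",
               lattice_model = "interdimer")

# best retained alignment of an isotype to a structure (across chains)
best_alignment <- function(isotype_seq, structure, min_identity, min_aligned) {
  alns <- lapply(names(structure$chains), function(ch)
    align_chain(isotype_seq, structure, ch, min_identity, min_aligned))
  alns <- Filter(Negate(is.null), alns)
  if (!length(alns)) return(NULL)
  scores <- vapply(alns, `[[`, numeric(1), "score")
  alns[[order(-scores, vapply(alns, `[[`, character(1), "chain_id"))[1]]]
}

#' Annotate a variant catalog with structural-location classes
#'
#' For every variant position: GTP-contact evidence is unioned over all
#' retained structures; interface evidence comes from the configured model
#' structures (`model_roles`); rSASA is taken from the highest-resolution
#' structure in which the position maps (resolution ties broken by
#' lexicographically smallest structure id; structures without a recorded
#' resolution sort last). Every variant receives exactly one class.
#'
#' @param catalog a [variant_catalog()].
#' @param structures list of `structure_record`s.
#' @param model_roles list of [model_role()] entries.
#' @param contact_cutoff heavy-atom contact distance (Angstrom).
#' @param rsasa_threshold surface cut (strict `>`).
#' @param ligand_codes GTP and analogue component codes.
#' @param min_identity,min_aligned chain-retention thresholds.
#' @param n_points SASA sampling density per atom.
#' @return data frame, one row per variant: `isotype, protein_change,
#'   label, location_class, rsasa, sources`.
#' @export
annotate_catalog <- function(catalog, structures, model_roles = list(),
                             contact_cutoff = 5.0, rsasa_threshold = 0.25,
                             ligand_codes = GTP_ANALOGUE_CODES,
                             min_identity = 70, min_aligned = 50,
                             n_points = 960) {
  stopifnot(inherits(catalog, "variant_catalog"))
  names(structures) <- vapply(structures, `[[`, character(1), "structure_id")

  # per-structure precomputation shared across isotypes
  gtp_sets <- lapply(structures, ligand_contact_set,
                     ligand_codes = ligand_codes, cutoff = contact_cutoff)
  iface_sets <- lapply(model_roles, function(mr) {
    st <- structures[[mr$structure_id]]
    if (is.null(st)) stop("model_roles references unknown structure: ", mr$structure_id)
    list(role = mr$role, structure_id = mr$structure_id, group_a = mr$group_a,
         contacts = interface_contact_set(st, mr$group_a, mr$group_b, contact_cutoff))
  })
  sasa_cache <- new.env(parent = emptyenv())
  get_rsasa <- function(structure_id, chain_id) {
    k <- paste(structure_id, chain_id, sep = "|")
    if (is.null(sasa_cache[[k]]))
      sasa_cache[[k]] <- relative_sasa(structures[[structure_id]], chain_id,
                                       n_points = n_points)
    sasa_cache[[k]]
  }

  v <- catalog$variants
  out <- data.frame(isotype = v$isotype,
                    protein_change = format_protein_change(v$wt_aa, v$position, v$mut_aa),
                    label = v$label,
                    location_class = NA_character_,
                    rsasa = NA_real_,
                    sources = NA_character_,
                    stringsAsFactors = FALSE)

  for (iso in unique(v$isotype)) {
    seq <- catalog$isotypes$sequence[match(iso, catalog$isotypes$gene_symbol)]
    alns <- lapply(structures, function(st)
      best_alignment(seq, st, min_identity, min_aligned))
    alns <- Filter(Negate(is.null), alns)
    rows <- which(v$isotype == iso)
    if (!length(alns)) {
      warning("no structure retained for isotype ", iso,
              "; all its variants are OUTSIDE_STRUCTURE")
      out$location_class[rows] <- "OUTSIDE_STRUCTURE"
      next
    }
    res_order <- order(
      vapply(alns, function(a) {
        r <- structures[[a$structure_id]]$resolution
        if (is.na(r)) Inf else r
      }, numeric(1)),
      vapply(alns, `[[`, character(1), "structure_id"))

    for (i in rows) {
      pos <- v$position[i]
      mapped_res <- lapply(alns, map_position, isotype_pos = pos)
      mapped <- !vapply(mapped_res, is.na, logical(1))
      ev <- list(mapped = any(mapped), gtp_contact = FALSE, intradimer = FALSE,
                 map_interface = FALSE, interdimer = FALSE, rsasa = NA_real_)
      srcs <- character()
      if (ev$mapped) {
        for (sid in names(alns)[mapped]) {
          a <- alns[[sid]]
          resno <- mapped_res[[sid]]
          g <- gtp_sets[[sid]]
          if (nrow(g) && any(g$chain == a$chain_id & g$resno == resno)) {
            ev$gtp_contact <- TRUE
            srcs <- c(srcs, paste0(sid, ":GTP"))
          }
        }
        for (fs in iface_sets) {
          sid <- fs$structure_id
          if (!sid %in% names(alns) || !mapped[[sid]]) next
          a <- alns[[sid]]
          if (!a$chain_id %in% fs$group_a) next
          resno <- mapped_res[[sid]]
          if (nrow(fs$contacts) &&
              any(fs$contacts$chain == a$chain_id & fs$contacts$resno == resno)) {
            ev[[role_flag[[fs$role]]]] <- TRUE
            srcs <- c(srcs, paste0(sid, ":", fs$role))
          }
        }
        for (k in res_order) {
          sid <- names(alns)[k]
          if (!mapped[[sid]]) next
          rs <- get_rsasa(sid, alns[[sid]]$chain_id)
          val <- rs[as.character(mapped_res[[sid]])]
          if (!is.na(val)) {
            ev$rsasa <- unname(val)
            srcs <- c(srcs, paste0(sid, ":rsasa"))
            break
          }
        }
      }
      out$location_class[i] <- classify_position(ev, rsasa_threshold)
      out$rsasa[i] <- ev$rsasa
      out$sources[i] <- paste(unique(srcs), collapse = ";")
    }
  }
  out
}
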