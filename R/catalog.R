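# Variant catalog: isotype registry, protein-change parsing, loading,
# validation, deduplication and stratification.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

PHENOTYPE_CLASSES <- c("neurodevelopmental", "other", "cancer_only", "non_disease")

#' Normalize a tubulin gene symbol
#'
#' Accepts upper/lower case HGNC-style symbols as well as the Greek-letter
#' notation common in the tubulin literature (e.g. `"TUBα1A"`,
#' `"TUBß8"`) and returns the HGNC-style symbol (e.g. `"TUBA1A"`,
#' `"TUBB8"`).
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_gene_symbol(c("TUBα1A", "TUBß8", "tubg1"))
#' @export
normalize_gene_symbol <- function(x) {
  stopifnot(is.character(x))
  out <- x
  for (greek in c("α", "a")) out <- sub(paste0("^TUB", greek), "TUBA", out, ignore.case = FALSE)
  for (greek in c("β", "ß", "b")) out <- sub(paste0("^TUB", greek), "TUBB", out)
  for (greek in c("γ", "g")) out <- sub(paste0("^TUB", greek), "TUBG", out)
  toupper(out)
}

#' Load the tubulin isotype registry
#'
#' The registry combines per-isotype metadata (family, phenotype
#' classification, gnomAD missense-constraint Z-score (MCM), reported variant
#' counts) with a protein sequence per isotype. The packaged metadata covers
#' the 19 human isotypes considered in the survey. The packaged sequence set
#' is *synthetic* (deterministically generated, see
#' [make_synthetic_registry_fasta()]); supply `fasta` to use real sequences.
#'
#' @param metadata path to a tab-separated metadata table. Defaults to the
#'   packaged table.
#' @param fasta path to a FASTA file with one sequence per `gene_symbol`.
#'   Defaults to the packaged synthetic sequences.
#' @return a data frame of class `isotype_registry` with columns
#'   `gene_symbol`, `family`, `n_pathogenic`, `n_gnomad`, `mcm`,
#'   `phenotype_class`, `sequence`.
#' @export
isotype_registry <- function(metadata = system.file("extdata", "tubulin_isotypes.tsv",
                                                    package = "tubulinvep"),
                             fasta = system.file("extdata", "synthetic_isotype_sequences.fasta",
                                                 package = "tubulinvep")) {
  meta <- read.delim(metadata, stringsAsFactors = FALSE)
  req <- c("gene_symbol", "family", "phenotype_class")
  if (!all(req %in% names(meta)))
    stop("registry metadata must contain columns: ", paste(req, collapse = ", "))
  meta$gene_symbol <- normalize_gene_symbol(meta$gene_symbol)
  bad <- setdiff(meta$phenotype_class, PHENOTYPE_CLASSES)
  if (length(bad)) stop("unknown phenotype_class: ", paste(bad, collapse = ", "))

  seqs <- read_fasta_sequences(fasta)
  names(seqs) <- normalize_gene_symbol(names(seqs))
  missing <- setdiff(meta$gene_symbol, names(seqs))
  if (length(missing))
    warning("no sequence for isotypes: ", paste(missing, collapse = ", "))
  meta$sequence <- unname(seqs[meta$gene_symbol])
  ok <- !is.na(meta$sequence) & !grepl(paste0("[^", paste(AA1, collapse = ""), "]"), meta$sequence)
  if (any(!ok & !is.na(meta$sequence)))
    stop("registry sequences contain non-canonical residue letters")
  class(meta) <- c("isotype_registry", class(meta))
  meta
}

read_fasta_sequences <- function(path) {
  fa <- Biostrings::readAAStringSet(path)
  setNames(as.character(fa), sub("\\s.*$", "", names(fa)))
}

#' Parse a protein-change token
#'
#' Tokens use the field's compact notation, e.g. `"V353I"`: wild-type
#' residue, 1-based position on the isotype sequence, mutant residue.
#'
#' @param token character vector of tokens.
#' @return a data frame with columns `wt_aa`, `position`, `mut_aa`.
#' @examples
#' parse_protein_change("V353I")
#' @export
parse_protein_change <- function(token) {
  stopifnot(is.character(token), length(token) >= 1)
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))
  out <- lapply(seq_along(token), function(i) {
    g <- m[[i]]
    if (length(g) != 4)
      stop("malformed protein change token: '", token[i], "'")
    wt <- toupper(g[2]); mut <- toupper(g[4]); pos <- as.integer(g[3])
    if (!(wt %in% AA1) || !(mut %in% AA1))
      stop("non-canonical residue letter in token: '", token[i], "'")
    if (pos < 1L)
      stop("position must be >= 1 in token: '", token[i], "'")
    if (wt == mut)
      stop("wild-type equals mutant residue in token: '", token[i], "'")
    data.frame(wt_aa = wt, position = pos, mut_aa = mut, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Format a protein-change token from its components
#' @param wt_aa,position,mut_aa components as returned by [parse_protein_change()].
#' @return character vector of tokens.
#' @export
format_protein_change <- function(wt_aa, position, mut_aa) {
  paste0(wt_aa, position, mut_aa)
}

#' Load and validate a variant table
#'
#' Reads a delimited file with columns `isotype`, `protein_change` (and
#' optionally `source`), validates each row against the isotype registry
#' (known isotype; wild-type letter matching the registry sequence at the
#' stated position), and returns the accepted records. Rejected rows are
#' reported via a `rejects` attribute and a message.
#'
#' @param path path to a CSV/TSV file (delimiter sniffed from the header).
#' @param label `"pathogenic"` or `"gnomad"`.
#' @param registry an [isotype_registry()].
#' @return data frame of variant records with columns `isotype`, `position`,
#'   `wt_aa`, `mut_aa`, `label`, `source`; attribute `rejects` holds a data
#'   frame of rejected rows with a `reason` column.
#' @export
load_variant_table <- function(path, label = c("pathogenic", "gnomad"), registry) {
  label <- match.arg(label)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("isotype", "protein_change") %in% names(raw)))
    stop("variant table must have columns 'isotype' and 'protein_change': ", path)
  if (is.null(raw$source)) raw$source <- NA_character_
  raw$isotype <- normalize_gene_symbol(as.character(raw$isotype))
  validate_variants(raw, label, registry)
}

validate_variants <- function(raw, label, registry) {
  keep <- logical(nrow(raw))
  reason <- character(nrow(raw))
  parsed <- data.frame(wt_aa = NA_character_, position = NA_integer_,
                       mut_aa = NA_character_)[rep(1, max(nrow(raw), 1)), , drop = FALSE]
  for (i in seq_len(nrow(raw))) {
    p <- tryCatch(parse_protein_change(raw$protein_change[i]), error = function(e) e)
    if (inherits(p, "error")) { reason[i] <- conditionMessage(p); next }
    j <- match(raw$isotype[i], registry$gene_symbol)
    if (is.na(j)) { reason[i] <- paste0("unknown isotype '", raw$isotype[i], "'"); next }
    seq <- registry$sequence[j]
    if (is.na(seq)) { reason[i] <- paste0("no sequence for isotype '", raw$isotype[i], "'"); next }
    if (p$position > nchar(seq)) { reason[i] <- "position beyond sequence length"; next }
    if (substr(seq, p$position, p$position) != p$wt_aa) {
      reason[i] <- paste0("wild-type mismatch: registry has ",
                          substr(seq, p$position, p$position), " at ", p$position)
      next
    }
    keep[i] <- TRUE
    parsed[i, ] <- p
  }
  out <- data.frame(isotype = raw$isotype[keep],
                    position = parsed$position[keep],
                    wt_aa = parsed$wt_aa[keep],
                    mut_aa = parsed$mut_aa[keep],
                    label = rep(label, sum(keep)),
                    source = raw$source[keep],
                    stringsAsFactors = FALSE)
  rejects <- cbind(raw[!keep, , drop = FALSE], reason = reason[!keep])
  if (nrow(rejects))
    message(nrow(rejects), " row(s) rejected while loading ", label, " variants")
  attr(out, "rejects") <- rejects
  out
}

#' Assemble a variant catalog
#'
#' @param variants data frame of variant records (rbind of
#'   [load_variant_table()] outputs).
#' @param registry an [isotype_registry()].
#' @return list of class `variant_catalog` with elements `variants` and
#'   `isotypes`.
#' @export
variant_catalog <- function(variants, registry) {
  stopifnot(all(c("isotype", "position", "wt_aa", "mut_aa", "label") %in% names(variants)))
  unknown <- setdiff(unique(variants$isotype), registry$gene_symbol)
  if (length(unknown))
    stop("variants reference isotypes absent from the registry: ",
         paste(unknown, collapse = ", "))
  structure(list(variants = variants, isotypes = registry),
            class = "variant_catalog")
}

variant_key <- function(v) {
  paste(v$isotype, v$position, v$wt_aa, v$mut_aa, sep = ":")
}

#' Remove substitutions present under both labels
#'
#' A substitution reported as pathogenic *and* observed in gnomAD is
#' uninformative for benchmarking; such records are removed from both sets.
#'
#' @param catalog a [variant_catalog()].
#' @return the catalog with overlapping substitutions dropped from both
#'   label sets; attribute `n_removed` counts dropped records.
#' @export
deduplicate_overlaps <- function(catalog) {
  stopifnot(inherits(catalog, "variant_catalog"))
  v <- catalog$variants
  key <- variant_key(v)
  path_keys <- unique(key[v$label == "pathogenic"])
  gnom_keys <- unique(key[v$label == "gnomad"])
  shared <- intersect(path_keys, gnom_keys)
  keep <- !(key %in% shared)
  out <- catalog
  out$variants <- v[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Isotypes meeting a minimum pathogenic-variant count
#'
#' @param catalog a [variant_catalog()].
#' @param min_pathogenic minimum number of distinct pathogenic records.
#' @return character vector of gene symbols, sorted.
#' @export
eligible_isotypes <- function(catalog, min_pathogenic) {
  stopifnot(inherits(catalog, "variant_catalog"), min_pathogenic >= 1)
  v <- catalog$variants
  counts <- table(v$isotype[v$label == "pathogenic"])
  sort(names(counts)[counts >= min_pathogenic])
}

#' Phenotype group of a disease-associated isotype
#'
#' Disease-linked isotypes are grouped as `neurodevelopmental` or `other`
#' following their phenotype classification; cancer-only and non-disease
#' isotypes cannot be grouped.
#'
#' @param isotype gene symbol(s).
#' @param registry an [isotype_registry()].
#' @return character vector of `"neurodevelopmental"` / `"other"`.
#' @export
phenotype_group <- function(isotype, registry) {
  isotype <- normalize_gene_symbol(isotype)
  j <- match(isotype, registry$gene_symbol)
  if (anyNA(j)) stop("unknown isotype: ", paste(isotype[is.na(j)], collapse = ", "))
  cls <- registry$phenotype_class[j]
  bad <- !(cls %in% c("neurodevelopmental", "other"))
  if (any(bad))
    stop("isotype(s) not groupable (cancer-only or non-disease): ",
         paste(isotype[bad], collapse = ", "))
  cls
}

#' Write a catalog to TSV and JSON
#' @param catalog a [variant_catalog()].
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @return invisibly, the variant data frame.
#' @export
write_catalog <- function(catalog, tsv = NULL, json = NULL) {
  v <- catalog$variants
  v$protein_change <- format_protein_change(v$wt_aa, v$position, v$mut_aa)
  if (!is.null(tsv))
    write.table(v, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(v, json, dataframe = "rows", auto_unbox = TRUE)
  invisible(v)
}
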