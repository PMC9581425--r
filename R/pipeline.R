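# Pipeline orchestration: run every stage from a config (YAML or list)
# and write the report bundle.

#' Load a pipeline config
#'
#' Relative paths in the config are resolved against the config file's
#' directory.
#'
#' @param path YAML config path.
#' @return named list with absolute input paths.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("registry_metadata", "registry_fasta", "catalog_csv",
                "scores_csv", "ddg_csv", "structures_dir")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]]))
      cfg[[key]] <- file.path(base, cfg[[key]])
  }
  cfg
}

validate_config <- function(cfg) {
  for (key in c("registry_metadata", "registry_fasta", "catalog_csv",
                "scores_csv", "ddg_csv", "structures_dir")) {
    if (is.null(cfg[[key]]))
      stop("config missing required entry '", key, "'")
    if (!file.exists(cfg[[key]]))
      stop("config entry '", key, "' points to a missing path: ", cfg[[key]])
  }
  stopifnot(cfg$contact_cutoff %||% 5 > 0, cfg$rsasa_threshold %||% 0.25 > 0)
  invisible(cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: catalog load + deduplication; structural annotation; location
#' enrichment; ddG group comparisons; stratified VEP benchmarking with
#' optimal thresholds; MCD ranking; manifest. Outputs are deterministic
#' given the config and inputs (re-runs are identical except the manifest
#' timestamp).
#'
#' @param config config list (see [read_pipeline_config()]) or YAML path.
#' @param out_dir output directory.
#' @return invisibly, a named list of output paths.
#' @export
run_all <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  catalog <- stage("catalog", {
    registry <- isotype_registry(cfg$registry_metadata, cfg$registry_fasta)
    raw <- read.delim(cfg$catalog_csv, sep = ",", stringsAsFactors = FALSE)
    parts <- lapply(c("pathogenic", "gnomad"), function(l) {
      sub <- raw[raw$label == l, , drop = FALSE]
      validate_variants(sub, l, registry)
    })
    deduplicate_overlaps(variant_catalog(do.call(rbind, parts), registry))
  })
  write_catalog(catalog, tsv = file.path(out_dir, "catalog.tsv"),
                json = file.path(out_dir, "catalog.json"))
  out$catalog <- file.path(out_dir, "catalog.tsv")
  out$catalog_json <- file.path(out_dir, "catalog.json")

  annotations <- stage("structure_map", {
    paths <- list.files(cfg$structures_dir, pattern = "\\.(pdb|cif)$",
                        full.names = TRUE)
    if (!length(paths)) stop("no structures found in ", cfg$structures_dir)
    structures <- lapply(sort(paths), parse_structure)
    roles <- lapply(cfg$model_roles, function(mr)
      model_role(mr$structure_id, mr$role, mr$group_a, mr$group_b))
    annotate_catalog(catalog, structures, roles,
                     contact_cutoff = cfg$contact_cutoff %||% 5.0,
                     rsasa_threshold = cfg$rsasa_threshold %||% 0.25)
  })
  out$annotation <- write_tsv(annotations, file.path(out_dir, "annotation.tsv"))

  out$enrichment <- stage("enrichment", {
    rep <- enrichment_report(annotations, catalog$isotypes,
                             min_pathogenic = cfg$min_pathogenic_enrich %||% 5)
    write_tsv(rep, file.path(out_dir, "enrichment.tsv"))
  })

  out$stability <- stage("stability", {
    ddg <- load_ddg_table(cfg$ddg_csv, catalog)
    write_tsv(ddg_report(ddg, catalog$isotypes,
                         min_pathogenic = cfg$min_pathogenic_enrich %||% 5),
              file.path(out_dir, "stability.tsv"))
  })

  bench <- stage("vep_benchmark", {
    tab <- read_vep_table(cfg$scores_csv,
                          inverse_predictors = cfg$inverse_predictors %||%
                            c("PROVEAN", "DeepSequence", "SIFT4G", "BLOSUM"))
    oriented <- orient_scores(tab)
    labs <- table_labels(oriented, catalog)
    keep <- !is.na(labs)
    oriented$scores <- oriented$scores[keep, , drop = FALSE]
    list(raw = tab, oriented = oriented, labels = labs[keep])
  })
  out$auc_global <- stage("vep_benchmark", {
    m <- stratified_auc(bench$oriented, catalog, "global")
    write_tsv(data.frame(predictor = rownames(m), auc = m[, 1]),
              file.path(out_dir, "auc_global.tsv"))
  })
  out$auc_isotype <- stage("vep_benchmark", {
    m <- stratified_auc(bench$oriented, catalog, "isotype",
                        min_pathogenic = cfg$min_pathogenic_auc %||% 10)
    write_tsv(data.frame(predictor = rownames(m), m, check.names = FALSE),
              file.path(out_dir, "auc_by_isotype.tsv"))
  })
  out$auc_phenotype <- stage("vep_benchmark", {
    m <- stratified_auc(bench$oriented, catalog, "phenotype_group")
    df <- data.frame(predictor = rownames(m), m, check.names = FALSE)
    cmp <- tryCatch(phenotype_group_auc_test(m), error = function(e) NULL)
    p <- file.path(out_dir, "auc_by_phenotype.tsv")
    write_tsv(df, p)
    if (!is.null(cmp))
      cat(sprintf("# paired signed-rank p = %.6g over %d predictors\n",
                  cmp$p_value, nrow(cmp$pairs)),
          file = p, append = TRUE)
    p
  })
  out$thresholds <- stage("vep_benchmark", {
    raw <- bench$raw
    keys <- rownames(bench$oriented$scores)
    thr <- lapply(colnames(raw$scores), function(p) {
      res <- tryCatch(
        optimal_native_threshold(raw$scores[keys, p], bench$labels,
                                 orientation = raw$orientation[[p]]),
        error = function(e) NULL)
      if (is.null(res)) NULL
      else res[c("threshold", "direction", "fpr", "tpr")]
    })
    names(thr) <- colnames(raw$scores)
    p <- file.path(out_dir, "thresholds.json")
    jsonlite::write_json(Filter(Negate(is.null), thr), p,
                         auto_unbox = TRUE, digits = NA)
    p
  })

  out$mcd <- stage("mcd_rank", {
    mcd <- mcd_table(bench$oriented)
    write_tsv(rank_pathogenic(mcd, catalog), file.path(out_dir, "mcd_ranking.tsv"))
  })

  out$manifest <- stage("manifest", {
    inputs <- unlist(cfg[c("registry_metadata", "registry_fasta", "catalog_csv",
                           "scores_csv", "ddg_csv")])
    manifest <- list(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      package_version = as.character(utils::packageVersion("tubulinvep")),
      r_version = R.version.string,
      config = cfg,
      input_md5 = as.list(tools::md5sum(inputs)),
      output_md5 = as.list(tools::md5sum(unlist(out))))
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
    p
  })
  invisible(out)
}
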