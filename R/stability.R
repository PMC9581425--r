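# Predicted folding-stability changes (FoldX-style ddG tables): ingestion
# and pathogenic-vs-gnomAD group comparisons. FoldX itself is never run;
# the module consumes tabulated output.

#' Load a ddG table and join it to the catalog
#'
#' Expects a CSV/TSV with columns `isotype`, `protein_change`, `ddg_fold`
#' (monomer) and `ddg_full` (biological assembly), both in kcal/mol with
#' positive values predicted destabilising. Rows that do not correspond to
#' a catalog variant are skipped with a message.
#'
#' @param path file path.
#' @param catalog a [variant_catalog()].
#' @return data frame `isotype, protein_change, ddg_fold, ddg_full, label`;
#'   attribute `orphans` holds the skipped rows.
#' @export
load_ddg_table <- function(path, catalog) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("isotype", "protein_change")
  if (!all(need %in% names(raw)))
    stop("ddG table must have columns isotype, protein_change: ", path)
  if (is.null(raw$ddg_fold) && is.null(raw$ddg_full))
    stop("ddG table must have at least one of ddg_fold / ddg_full")
  raw$isotype <- normalize_gene_symbol(raw$isotype)
  v <- catalog$variants
  cat_key <- paste(v$isotype, format_protein_change(v$wt_aa, v$position, v$mut_aa), sep = ":")
  row_key <- paste(raw$isotype, raw$protein_change, sep = ":")
  j <- match(row_key, cat_key)
  orphans <- raw[is.na(j), , drop = FALSE]
  if (nrow(orphans))
    message(nrow(orphans), " ddG row(s) skipped: no matching catalog variant")
  out <- raw[!is.na(j), , drop = FALSE]
  if (!nrow(out)) stop("no ddG rows join to the catalog")
  out$label <- v$label[j[!is.na(j)]]
  rownames(out) <- NULL
  attr(out, "orphans") <- orphans
  out
}

#' Compare ddG between pathogenic and gnomAD variants
#'
#' Applies an unpaired rank-sum test to the chosen metric within a stratum
#' and reports group means/medians. Metrics: `fold` (monomer), `full`
#' (assembly), or their absolute values `abs_fold` / `abs_full` (magnitude
#' of perturbation regardless of direction).
#'
#' @param records output of [load_ddg_table()] (or any data frame with
#'   `isotype`, `label` and the ddG columns).
#' @param registry an [isotype_registry()] (family lookup), or `NULL` to
#'   treat `stratum` as isotype-only.
#' @param stratum `"global"`, a family name, or a gene symbol.
#' @param metric one of `"fold"`, `"full"`, `"abs_fold"`, `"abs_full"`.
#' @return a `tubulin_test` with a `summary` element
#'   (per-label mean, median, n).
#' @export
ddg_group_comparison <- function(records, registry = NULL, stratum = "global",
                                 metric = c("fold", "full", "abs_fold", "abs_full")) {
  metric <- match.arg(metric)
  col <- if (grepl("fold$", metric)) "ddg_fold" else "ddg_full"
  if (is.null(records[[col]])) stop("metric column '", col, "' absent from records")
  df <- records
  if (stratum != "global") {
    fam <- if (!is.null(registry))
      registry$family[match(df$isotype, registry$gene_symbol)] else NA_character_
    df <- df[df$isotype == stratum | (!is.na(fam) & fam == stratum), , drop = FALSE]
  }
  x <- df[[col]]
  if (startsWith(metric, "abs")) x <- abs(x)
  keep <- !is.na(x)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " record(s) lacking ", col, " dropped for this comparison")
  x <- x[keep]; lab <- df$label[keep]
  if (length(unique(lab)) < 2)
    stop("stratum '", stratum, "' lacks one of the labels")
  res <- rank_sum_test(x[lab == "pathogenic"], x[lab == "gnomad"])
  res$summary <- do.call(rbind, lapply(c("pathogenic", "gnomad"), function(l) {
    data.frame(label = l, mean = mean(x[lab == l]), median = stats::median(x[lab == l]),
               n = sum(lab == l), stringsAsFactors = FALSE)
  }))
  res$metric <- metric
  res
}

#' ddG comparison report across strata
#'
#' @param records output of [load_ddg_table()].
#' @param registry an [isotype_registry()].
#' @param min_pathogenic minimum pathogenic count for an isotype stratum
#'   (default 5, the usual per-isotype plotting filter).
#' @param metric as in [ddg_group_comparison()].
#' @return data frame `stratum, metric, mean_path, mean_gnomad, n_path,
#'   n_gnomad, p`.
#' @export
ddg_report <- function(records, registry, min_pathogenic = 5, metric = "fold") {
  fams <- unique(registry$family[match(records$isotype, registry$gene_symbol)])
  isos <- names(which(table(records$isotype[records$label == "pathogenic"]) >= min_pathogenic))
  rows <- lapply(c("global", fams, isos), function(s) {
    res <- tryCatch(ddg_group_comparison(records, registry, s, metric),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(stratum = s, metric = metric,
               mean_path = res$summary$mean[1], mean_gnomad = res$summary$mean[2],
               n_path = res$summary$n[1], n_gnomad = res$summary$n[2],
               p = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
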