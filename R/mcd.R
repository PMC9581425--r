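# Mean cumulative distribution (MCD) score: per-predictor cumulative ranks
# over the pooled pathogenic + gnomAD dataset, averaged per mutation.

#' Cumulative-distribution rank of each score within its vector
#'
#' For each non-missing score `s`, returns the proportion of non-missing
#' scores less than or equal to `s` (values in (0, 1]); missing scores stay
#' missing.
#'
#' @param scores numeric vector.
#' @return numeric vector of the same length.
#' @examples
#' cumulative_rank(c(10, 20, 30))  # 1/3, 2/3, 1
#' @export
cumulative_rank <- function(scores) {
  ok <- !is.na(scores)
  if (!any(ok)) stop("all scores missing")
  n <- sum(ok)
  out <- rep(NA_real_, length(scores))
  out[ok] <- rank(scores[ok], ties.method = "max") / n
  out
}

#' Per-mutation MCD scores over a pooled score table
#'
#' Scores must be oriented (higher = more damaging) and the table must pool
#' pathogenic and gnomAD variants: each predictor column is converted to
#' cumulative-distribution ranks over the pooled dataset, and each
#' mutation's MCD is the mean of its available ranks. MCD runs from near 0
#' (predicted mildest) to 1 (predicted most disruptive). Rows with no
#' available score are excluded (and reported via the `excluded` attribute).
#'
#' @param table an oriented [vep_table()] (see [orient_scores()]).
#' @return data frame with columns `key`, `mcd`, `n_predictors_used`, plus
#'   the per-predictor rank matrix as attribute `ranks`.
#' @export
mcd_table <- function(table) {
  stopifnot(inherits(table, "vep_table"))
  if (any(table$orientation == "inverse"))
    stop("orient the table first (orient_scores)")
  ranks <- vapply(colnames(table$scores),
                  function(p) cumulative_rank(table$scores[, p]),
                  numeric(nrow(table$scores)))
  ranks <- matrix(ranks, nrow = nrow(table$scores),
                  dimnames = dimnames(table$scores))
  used <- rowSums(!is.na(ranks))
  excluded <- rownames(ranks)[used == 0]
  if (length(excluded))
    message(length(excluded), " mutation(s) excluded from MCD: no scores available")
  keep <- used >= 1
  out <- data.frame(key = rownames(ranks)[keep],
                    mcd = rowMeans(ranks[keep, , drop = FALSE], na.rm = TRUE),
                    n_predictors_used = used[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ranks") <- ranks
  attr(out, "excluded") <- excluded
  out
}

#' Rank pathogenic mutations by MCD, worst-predicted first
#'
#' Pathogenic variants with the lowest MCD are the ones the predictor
#' ensemble considers most benign, i.e. the most poorly predicted.
#' Ties are broken lexicographically by (isotype, protein_change).
#'
#' @param mcd output of [mcd_table()].
#' @param catalog a [variant_catalog()].
#' @return data frame `isotype, protein_change, label, mcd,
#'   n_predictors_used` sorted ascending by MCD, pathogenic records only.
#' @export
rank_pathogenic <- function(mcd, catalog) {
  v <- catalog$variants
  key <- paste(v$isotype, format_protein_change(v$wt_aa, v$position, v$mut_aa), sep = ":")
  lab <- setNames(v$label, key)[mcd$key]
  out <- data.frame(isotype = sub(":.*$", "", mcd$key),
                    protein_change = sub("^.*:", "", mcd$key),
                    label = unname(lab),
                    mcd = mcd$mcd,
                    n_predictors_used = mcd$n_predictors_used,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$label) & out$label == "pathogenic", , drop = FALSE]
  out <- out[order(out$mcd, out$isotype, out$protein_change), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare MCD between pathogenic and gnomAD variants within a stratum
#'
#' @param mcd output of [mcd_table()].
#' @param catalog a [variant_catalog()].
#' @param stratum `"global"`, a family name, or a gene symbol.
#' @return a `tubulin_test` (unpaired rank-sum).
#' @export
mcd_group_comparison <- function(mcd, catalog, stratum = "global") {
  v <- catalog$variants
  key <- paste(v$isotype, format_protein_change(v$wt_aa, v$position, v$mut_aa), sep = ":")
  meta <- data.frame(key = key, label = v$label, isotype = v$isotype,
                     family = catalog$isotypes$family[match(v$isotype, catalog$isotypes$gene_symbol)],
                     stringsAsFactors = FALSE)
  df <- merge(mcd, meta, by = "key")
  if (stratum != "global")
    df <- df[df$isotype == stratum | df$family == stratum, , drop = FALSE]
  if (length(unique(df$label)) < 2)
    stop("stratum '", stratum, "' lacks one of the labels")
  rank_sum_test(df$mcd[df$label == "pathogenic"], df$mcd[df$label == "gnomad"])
}
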