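# Benchmarking of variant effect predictor (VEP) score tables:
# orientation handling, ROC/AUC, stratified AUC matrices, native-scale
# optimal thresholds, missing-score accounting.

#' Construct a VEP score table
#'
#' A wide mutation-by-predictor score matrix. Some predictors operate on an
#' inverse scale (more damaging = lower score, e.g. PROVEAN, DeepSequence,
#' SIFT4G, BLOSUM); their columns carry an `"inverse"` orientation flag.
#'
#' @param scores numeric matrix; rows named by mutation key
#'   (`"ISOTYPE:PROTEINCHANGE"`), columns by predictor. `NA` = missing score.
#' @param orientation named character vector (`"direct"` / `"inverse"`), one
#'   entry per predictor; predictors not named are `direct`.
#' @return object of class `vep_table`.
#' @export
vep_table <- function(scores, orientation = character()) {
  stopifnot(is.matrix(scores), ncol(scores) >= 1,
            !is.null(colnames(scores)), !is.null(rownames(scores)))
  ori <- setNames(rep("direct", ncol(scores)), colnames(scores))
  if (length(orientation)) {
    if (is.null(names(orientation)))
      stop("orientation must be a named vector")
    unknown <- setdiff(names(orientation), colnames(scores))
    if (length(unknown))
      stop("orientation names absent from table: ", paste(unknown, collapse = ", "))
    stopifnot(all(orientation %in% c("direct", "inverse")))
    ori[names(orientation)] <- orientation
  }
  structure(list(scores = scores, orientation = ori), class = "vep_table")
}

#' Read a wide VEP score CSV
#'
#' First two columns must be `isotype` and `protein_change`; remaining
#' columns are predictor scores.
#'
#' @param path CSV/TSV path.
#' @param inverse_predictors predictor names flagged as inverse-scale.
#' @return a [vep_table()].
#' @export
read_vep_table <- function(path,
                           inverse_predictors = c("PROVEAN", "DeepSequence",
                                                  "SIFT4G", "BLOSUM")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("isotype", "protein_change") %in% names(raw)[1:2]))
    stop("first two columns must be isotype, protein_change: ", path)
  keys <- paste(normalize_gene_symbol(raw$isotype), raw$protein_change, sep = ":")
  m <- as.matrix(raw[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- keys
  inv <- intersect(inverse_predictors, colnames(m))
  vep_table(m, setNames(rep("inverse", length(inv)), inv))
}

#' Orient all predictor columns to "higher = more damaging"
#'
#' Inverse-flagged columns are multiplied by -1 and re-flagged as direct;
#' direct columns are untouched.
#'
#' @param table a [vep_table()].
#' @return the oriented [vep_table()].
#' @export
orient_scores <- function(table) {
  stopifnot(inherits(table, "vep_table"))
  inv <- names(table$orientation)[table$orientation == "inverse"]
  table$scores[, inv] <- -table$scores[, inv, drop = FALSE]
  table$orientation[inv] <- "direct"
  table
}

#' ROC curve and AUC for one score vector
#'
#' Pathogenic variants are the positives, gnomAD the negatives. The AUC is
#' the rank statistic (pairs with the positive scoring higher, ties counted
#' half), which equals the trapezoidal area under the unique-threshold ROC
#' curve. Missing scores are dropped.
#'
#' @param scores numeric vector, oriented so higher = more damaging.
#' @param labels logical or character vector; `TRUE`/`"pathogenic"` =
#'   positive.
#' @param stratum label used in error messages.
#' @return list of class `roc_result` with `fpr`, `tpr`, `thresholds`
#'   (descending, one point per unique score plus the (0,0) anchor), `auc`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, stratum = "global") {
  pos <- if (is.logical(labels)) labels else labels == "pathogenic"
  keep <- !is.na(scores)
  scores <- scores[keep]; pos <- pos[keep]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("single-class input in stratum '", stratum, "'")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(pos & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!pos & scores >= t), numeric(1))
  structure(list(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                 thresholds = c(Inf, thr), auc = auc,
                 n_pos = n_pos, n_neg = n_neg, stratum = stratum),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC [", x$stratum, "]: AUC = ", sprintf("%.4f", x$auc),
      " (", x$n_pos, " pathogenic vs ", x$n_neg, " gnomAD)\n", sep = "")
  invisible(x)
}

# labels for the rows of a vep_table, looked up from a catalog
table_labels <- function(table, catalog) {
  v <- catalog$variants
  key <- paste(v$isotype, format_protein_change(v$wt_aa, v$position, v$mut_aa), sep = ":")
  setNames(v$label, key)[rownames(table$scores)]
}

#' AUC matrix per predictor and stratum
#'
#' Computes the AUC of every predictor within every stratum: globally, per
#' isotype (subject to a minimum pathogenic-count filter), or per phenotype
#' group (neurodevelopmental vs other). Strata use only their own gnomAD
#' variants as negatives. Cells whose stratum lacks either class, or where
#' the predictor has no usable scores, are `NA` and logged in the
#' `dropped` attribute.
#'
#' @param table an oriented [vep_table()] (see [orient_scores()]).
#' @param catalog a [variant_catalog()] supplying labels and isotypes.
#' @param stratifier `"global"`, `"isotype"` or `"phenotype_group"`.
#' @param min_pathogenic minimum pathogenic count for isotype strata
#'   (default 10, the usual per-isotype benchmarking filter).
#' @return numeric matrix predictor x stratum, with attribute `dropped`.
#' @export
stratified_auc <- function(table, catalog,
                           stratifier = c("global", "isotype", "phenotype_group"),
                           min_pathogenic = 10) {
  stratifier <- match.arg(stratifier)
  stopifnot(inherits(table, "vep_table"))
  if (any(table$orientation == "inverse"))
    stop("orient the table first (orient_scores)")
  labs <- table_labels(table, catalog)
  if (anyNA(labs))
    stop(sum(is.na(labs)), " table rows not present in the catalog")
  iso <- sub(":.*$", "", rownames(table$scores))

  strata <- switch(stratifier,
    global = list(global = seq_along(labs)),
    isotype = {
      keep <- eligible_isotypes(catalog, min_pathogenic)
      idx <- split(seq_along(labs), iso)
      idx[names(idx) %in% keep]
    },
    phenotype_group = {
      grp <- vapply(iso, function(g) {
        tryCatch(phenotype_group(g, catalog$isotypes), error = function(e) NA_character_)
      }, character(1))
      idx <- split(seq_along(labs)[!is.na(grp)], grp[!is.na(grp)])
      idx
    })
  if (!length(strata)) stop("stratification produced no strata")

  preds <- colnames(table$scores)
  out <- matrix(NA_real_, length(preds), length(strata),
                dimnames = list(preds, names(strata)))
  dropped <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    for (p in preds) {
      res <- tryCatch(roc_auc(table$scores[idx, p], labs[idx], stratum = s),
                      error = function(e) e)
      if (inherits(res, "error")) {
        dropped[[paste(p, s, sep = "|")]] <- conditionMessage(res)
      } else out[p, s] <- res$auc
    }
  }
  attr(out, "dropped") <- dropped
  out
}

#' Paired comparison of predictor performance between phenotype groups
#'
#' Pairs each predictor's AUC on neurodevelopmental-linked isotypes with its
#' AUC on other-disease isotypes and applies a paired signed-rank test.
#' Predictors missing either group AUC are excluded.
#'
#' @param auc_matrix output of [stratified_auc()] with
#'   `stratifier = "phenotype_group"`.
#' @return a `tubulin_test`, with the per-predictor AUC pairs attached as
#'   `pairs`.
#' @export
phenotype_group_auc_test <- function(auc_matrix) {
  need <- c("neurodevelopmental", "other")
  if (!all(need %in% colnames(auc_matrix)))
    stop("matrix must contain both phenotype-group columns")
  pairs <- auc_matrix[, need, drop = FALSE]
  pairs <- pairs[complete.cases(pairs), , drop = FALSE]
  if (!nrow(pairs)) stop("no predictor has an AUC in both groups")
  res <- signed_rank_test(pairs[, 1] - pairs[, 2])
  res$pairs <- pairs
  res
}

#' Optimal decision threshold on the predictor's native scale
#'
#' Candidate thresholds are midpoints between adjacent distinct oriented
#' scores plus the two infinities; the threshold minimising the Euclidean
#' distance to the ROC top-left corner, sqrt(fpr^2 + (1-tpr)^2), is chosen
#' (ties broken toward higher specificity, i.e. lower fpr). For
#' inverse-scale predictors the threshold is reported back on the native
#' scale with direction `"below"` (scores lower than the threshold call
#' pathogenic); direct predictors get direction `"above"`.
#'
#' @param scores native-scale scores (as produced by the predictor).
#' @param labels as in [roc_auc()].
#' @param orientation `"direct"` or `"inverse"`.
#' @return list with `threshold` (native scale), `direction`, `fpr`, `tpr`,
#'   `distance`.
#' @export
optimal_native_threshold <- function(scores, labels, orientation = c("direct", "inverse")) {
  orientation <- match.arg(orientation)
  pos <- if (is.logical(labels)) labels else labels == "pathogenic"
  keep <- !is.na(scores)
  s <- scores[keep]; pos <- pos[keep]
  if (!sum(pos) || !sum(!pos)) stop("both classes required for a threshold")
  oriented <- if (orientation == "inverse") -s else s

  u <- sort(unique(oriented))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  fpr <- vapply(cand, function(t) sum(!pos & oriented >= t) / n_neg, numeric(1))
  tpr <- vapply(cand, function(t) sum(pos & oriented >= t) / n_pos, numeric(1))
  dist <- sqrt(fpr^2 + (1 - tpr)^2)
  ord <- order(dist, fpr)  # tie -> higher specificity
  best <- ord[1]
  thr_oriented <- cand[best]
  list(threshold = if (orientation == "inverse") -thr_oriented else thr_oriented,
       direction = if (orientation == "inverse") "below" else "above",
       fpr = fpr[best], tpr = tpr[best], distance = dist[best])
}

#' Fraction of missing scores per predictor
#'
#' @param table a [vep_table()].
#' @return named numeric vector of per-column missing fractions.
#' @export
missingness <- function(table) {
  stopifnot(inherits(table, "vep_table"), nrow(table$scores) >= 1)
  colMeans(is.na(table$scores))
}
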