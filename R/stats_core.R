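# Exact and rank-based statistics: 2x2 Fisher tests, unpaired rank-sum,
# paired signed-rank, and the per-location enrichment analysis.

new_test_result <- function(statistic, p_value, method, n, extra = list()) {
  stopifnot(p_value > 0, p_value <= 1)
  structure(c(list(statistic = unname(statistic), p_value = unname(p_value),
                   method = method, n = n), extra),
            class = "tubulin_test")
}

#' @export
print.tubulin_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic), ", p = ",
      format.pval(x$p_value), " (n = ", paste(x$n, collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Rows are the variant labels (pathogenic, gnomAD), columns membership in a
#' structural-location class. The two-sided p-value sums hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table.
#'
#' @param a,b,c,d cell counts: `a`,`b` = pathogenic in/not in class;
#'   `c`,`d` = gnomAD in/not in class. A 2x2 matrix may be given as `a`.
#' @return a `tubulin_test` with the conditional odds-ratio estimate as the
#'   statistic.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), nrow = 2)
  }
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cell counts must be non-negative integers")
  if (sum(tab) < 1) stop("table total must be >= 1")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  new_test_result(ft$estimate, ft$p.value, "fisher_2x2",
                  n = c(sum(tab[1, ]), sum(tab[2, ])))
}

#' Unpaired two-sample rank-sum (Mann-Whitney/Wilcoxon) test
#'
#' Exact enumeration when the pooled sample size is at most `exact_max` and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric vectors (NAs dropped).
#' @param exact_max pooled-size limit for the exact path.
#' @return a `tubulin_test` (statistic = Mann-Whitney U for `x`).
#' @export
rank_sum_test <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                                            alternative = "two.sided"))
  new_test_result(wt$statistic, wt$p.value, "rank_sum",
                  n = c(length(x), length(y)), extra = list(exact = exact))
}

#' Paired signed-rank (Wilcoxon) test on differences
#'
#' Zero differences are dropped. Exact enumeration for up to `exact_max`
#' nonzero untied differences; otherwise the normal approximation with tie
#' and continuity corrections.
#'
#' @param paired_diffs numeric vector of paired differences.
#' @param exact_max nonzero-difference limit for the exact path.
#' @return a `tubulin_test` (statistic = V, sum of positive ranks).
#' @export
signed_rank_test <- function(paired_diffs, exact_max = 15) {
  d <- paired_diffs[!is.na(paired_diffs)]
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE,
                                            alternative = "two.sided"))
  new_test_result(wt$statistic, wt$p.value, "signed_rank",
                  n = length(d), extra = list(exact = exact))
}

significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Per-location enrichment of pathogenic vs gnomAD variants
#'
#' For every structural-location class observed in the stratum, tests a 2x2
#' table (in-class vs not-in-class by pathogenic vs gnomAD) with a
#' two-sided Fisher's exact test, and reports which label is enriched
#' (odds ratio above/below 1) together with significance stars at
#' 0.05/0.01/0.001/0.0001. No multiple-testing correction is applied.
#'
#' @param annotations data frame with columns `label` and `location_class`
#'   (one row per variant), e.g. the output of [annotate_catalog()].
#' @param classes classes to test; defaults to those present.
#' @return data frame with one row per class:
#'   `location_class, n_path, n_gnomad, odds_ratio, p, stars, direction`.
#' @export
location_enrichment <- function(annotations, classes = NULL) {
  stopifnot(all(c("label", "location_class") %in% names(annotations)))
  labs <- annotations$label
  if (length(unique(labs)) < 2)
    stop("enrichment requires both pathogenic and gnomad variants in the stratum")
  if (is.null(classes)) classes <- sort(unique(annotations$location_class))
  n_path_tot <- sum(labs == "pathogenic")
  n_gnom_tot <- sum(labs == "gnomad")
  rows <- lapply(classes, function(cl) {
    inc <- annotations$location_class == cl
    a <- sum(inc & labs == "pathogenic")
    b <- n_path_tot - a
    cc <- sum(inc & labs == "gnomad")
    d <- n_gnom_tot - cc
    res <- fisher_exact_2x2(a, b, cc, d)
    data.frame(location_class = cl, n_path = a, n_gnomad = cc,
               odds_ratio = res$statistic, p = res$p_value,
               stars = significance_stars(res$p_value),
               direction = if (res$statistic > 1) "pathogenic"
                           else if (res$statistic < 1) "gnomad" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "totals") <- c(pathogenic = n_path_tot, gnomad = n_gnom_tot)
  rownames(out) <- NULL
  out
}

#' Enrichment report across strata
#'
#' Runs [location_enrichment()] per family and per isotype and binds the
#' results into one report table.
#'
#' @param annotations data frame with columns `label`, `location_class`,
#'   `isotype`.
#' @param registry an [isotype_registry()] (for family lookup).
#' @param min_pathogenic strata with fewer pathogenic variants are skipped.
#' @return data frame with a leading `stratum` column.
#' @export
enrichment_report <- function(annotations, registry, min_pathogenic = 5) {
  fam <- registry$family[match(annotations$isotype, registry$gene_symbol)]
  strata <- c(split(seq_len(nrow(annotations)), fam),
              split(seq_len(nrow(annotations)), annotations$isotype))
  rows <- lapply(names(strata), function(s) {
    idx <- strata[[s]]
    ann <- annotations[idx, , drop = FALSE]
    if (sum(ann$label == "pathogenic") < min_pathogenic) return(NULL)
    if (length(unique(ann$label)) < 2) return(NULL)
    cbind(stratum = s, location_enrichment(ann))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
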