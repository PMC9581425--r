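# Shared fixtures and independent oracles used across the suite.

# --- tiny registry / catalog builders -------------------------------------

toy_registry <- function(sequences, phenotype = NULL, family = NULL) {
  n <- length(sequences)
  reg <- data.frame(
    gene_symbol = names(sequences),
    family = family %||_% rep("alpha", n),
    n_pathogenic = 10, n_gnomad = 10, mcm = 1,
    phenotype_class = phenotype %||_% rep("neurodevelopmental", n),
    sequence = unname(sequences),
    stringsAsFactors = FALSE)
  class(reg) <- c("isotype_registry", class(reg))
  reg
}

`%||_%` <- function(a, b) if (is.null(a)) b else a

make_variants_df <- function(registry, isotype, positions, mut = NULL,
                             label = "pathogenic") {
  seqc <- strsplit(registry$sequence[match(isotype, registry$gene_symbol)], "")[[1]]
  wt <- seqc[positions]
  if (is.null(mut))
    mut <- vapply(wt, function(w) setdiff(tubulinvep:::AA1, w)[1], character(1))
  out <- data.frame(isotype = isotype, position = positions, wt_aa = wt,
                    mut_aa = mut, label = label, source = "test",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# minimal structure_record built directly from a sequence (CA-only chain)
chain_only_record <- function(seqs, structure_id = "mini", resolution = 2.0,
                              spacing = 3.8) {
  atoms <- do.call(rbind, lapply(names(seqs), function(ch) {
    letters1 <- strsplit(seqs[[ch]], "")[[1]]
    data.frame(chain = ch, resno = seq_along(letters1),
               resid = bio3d::aa123(letters1), resid1 = letters1,
               atom = "CA", element = "C",
               x = (seq_along(letters1) - 1) * spacing, y = 0, z = 0,
               het = FALSE, comp = bio3d::aa123(letters1),
               stringsAsFactors = FALSE)
  }))
  chains <- lapply(split(atoms, atoms$chain), function(a)
    a[order(a$resno), c("resno", "resid1")])
  structure(list(structure_id = structure_id, resolution = resolution,
                 atoms = atoms, chains = chains, ligands = list()),
            class = "structure_record")
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(tubulinvep:::AA1, n, replace = TRUE), collapse = "")
}

# --- independent oracles ---------------------------------------------------

# two-sided Fisher p by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# two-sided rank-sum p by enumeration of all rank assignments (no ties)
rank_sum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  r <- rank(pooled)
  us <- apply(combos, 2, function(idx) sum(sort(r)[idx]) - nx * (nx + 1) / 2)
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# two-sided signed-rank p by enumeration of all sign patterns (no ties)
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  lo <- mean(vs <= v_obs); hi <- mean(vs >= v_obs)
  min(1, 2 * min(lo, hi))
}

# AUC by brute-force pair counting
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# trapezoidal area under an ROC curve
trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# all-pairs interchain contact oracle
contact_oracle <- function(structure, group_a, group_b, cutoff) {
  at <- structure$atoms[toupper(structure$atoms$element) != "H", ]
  a <- at[!at$het & at$chain %in% group_a, ]
  b <- at[at$chain %in% group_b, ]
  hits <- character()
  for (i in seq_len(nrow(a))) {
    d <- sqrt((b$x - a$x[i])^2 + (b$y - a$y[i])^2 + (b$z - a$z[i])^2)
    if (any(d <= cutoff)) hits <- c(hits, paste(a$chain[i], a$resno[i]))
  }
  sort(unique(hits))
}
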