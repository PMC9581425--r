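# Shrake-Rupley solvent-accessible surface area and relative SASA against
# per-residue-type theoretical maxima (Tien et al. 2013).

# Theoretical maximum ASA (A^2) per residue type, Gly-X-Gly context.
TIEN_MAX_ASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

atom_radii <- function(elements, default_radius = 1.70) {
  r <- VDW_RADII[toupper(elements)]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(elements[is.na(r)]), collapse = ", "),
            "; using default radius ", default_radius, " A")
    r[is.na(r)] <- default_radius
  }
  unname(r)
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples points on each atom's solvent-expanded sphere (radius + probe)
#' and counts those not buried inside any neighbouring atom's expanded
#' sphere.
#'
#' @param xyz numeric matrix (n x 3) of heavy-atom coordinates in Angstrom.
#' @param elements character vector of element symbols (length n).
#' @param probe probe radius in Angstrom (water = 1.4).
#' @param n_points sample points per atom.
#' @param default_radius radius used for unknown elements (with a warning).
#' @return numeric vector of per-atom SASA in A^2.
#' @export
atom_sasa <- function(xyz, elements, probe = 1.4, n_points = 960,
                      default_radius = 1.70) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, nrow(xyz) == length(elements))
  n <- nrow(xyz)
  radii <- atom_radii(elements, default_radius)
  rext <- radii + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)
  max_reach <- max(rext)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rext[i] + max_reach)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < rext[i] + rext[nb]]
    sp <- pts * rext[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 + (sp[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > rext[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    out[i] <- 4 * pi * rext[i]^2 * frac
  }
  out
}

#' Relative solvent accessibility per residue of one chain
#'
#' Computes Shrake-Rupley SASA for the chain's residues in the context of
#' every heavy atom of the structure (other chains and ligands occlude),
#' then divides each residue's summed SASA by the theoretical maximum for
#' its residue type. Values can slightly exceed 1 for very exposed
#' residues.
#'
#' @param structure a `structure_record` from [parse_structure()].
#' @param chain_id chain identifier.
#' @param probe,n_points,default_radius passed to [atom_sasa()].
#' @return named numeric vector of rSASA keyed by residue number.
#' @export
relative_sasa <- function(structure, chain_id, probe = 1.4, n_points = 960,
                          default_radius = 1.70) {
  stopifnot(inherits(structure, "structure_record"))
  at <- structure$atoms
  if (!chain_id %in% at$chain) stop("chain '", chain_id, "' not in structure")
  heavy <- toupper(at$element) != "H"
  at <- at[heavy, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  sasa <- atom_sasa(xyz, at$element, probe = probe, n_points = n_points,
                    default_radius = default_radius)
  sel <- at$chain == chain_id & !at$het
  res_sasa <- tapply(sasa[sel], at$resno[sel], sum)
  letters1 <- at$resid1[sel][match(names(res_sasa), at$resno[sel])]
  ref <- TIEN_MAX_ASA[letters1]
  ref[is.na(ref)] <- mean(TIEN_MAX_ASA)
  out <- as.numeric(res_sasa) / as.numeric(ref)
  names(out) <- names(res_sasa)
  out
}
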