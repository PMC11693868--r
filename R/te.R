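#' Gene-level translational efficiency
#'
#' TE is the ratio of ribosome-associated to cytosolic abundance (FPKM).
#' A gene is eligible when its cytosolic FPKM reaches `min_fpkm` (the
#' denominator is then well defined); ineligible genes are absent from the
#' output.
#'
#' @param cyto_fpkm,ribo_fpkm Named per-gene FPKM vectors for one condition.
#' @param min_fpkm Cytosolic eligibility threshold (default 1).
#' @return Named TE vector over eligible genes.
#' @export
compute_te <- function(cyto_fpkm, ribo_fpkm, min_fpkm = 1) {
  genes <- names(cyto_fpkm)
  if (is.null(genes) || !identical(genes, names(ribo_fpkm))) {
    stop("cyto_fpkm and ribo_fpkm must be named over the same genes")
  }
  keep <- cyto_fpkm >= min_fpkm & cyto_fpkm > 0
  ribo_fpkm[keep] / cyto_fpkm[keep]
}

#' Normalize TE values to [0, 1]
#'
#' `rank`: empirical quantile `(rank - 1) / (n - 1)` with average ranks for
#' ties (invariant to monotone transforms, idempotent, robust to the heavy
#' right tail of TE ratios). `minmax`: `(x - min) / (max - min)`.
#'
#' @param te Named TE vector.
#' @param method `"rank"` (default) or `"minmax"`.
#' @return Named vector in [0, 1].
#' @export
normalize_te <- function(te, method = c("rank", "minmax")) {
  method <- match.arg(method)
  n <- length(te)
  if (n == 0) return(te)
  if (method == "rank") {
    if (n == 1) return(stats::setNames(0.5, names(te)))
    (rank(te, ties.method = "average") - 1) / (n - 1)
  } else {
    if (n < 2) stop("minmax normalization needs at least 2 values")
    rng <- range(te)
    if (rng[1] == rng[2]) {
      warning("all TE values identical; minmax maps everything to 0.5")
      return(stats::setNames(rep(0.5, n), names(te)))
    }
    (te - rng[1]) / (rng[2] - rng[1])
  }
}

#' Differential-TE calling on normalized values
#'
#' Over the common-gene set, flags `up_A` when
#' `te_norm_A - te_norm_B > delta_threshold`, `up_B` symmetrically, `ns`
#' otherwise (so `ns` iff `|delta| <= delta_threshold`).
#'
#' @param te_norm_a,te_norm_b Named normalized TE vectors over the same
#'   genes.
#' @param delta_threshold Absolute normalized-TE difference required
#'   (default 0.5).
#' @return data.frame with `gene_id`, `te_norm_a`, `te_norm_b`, `delta`
#'   (A minus B), `flag`.
#' @export
call_differential_te <- function(te_norm_a, te_norm_b,
                                 delta_threshold = 0.5) {
  genes <- names(te_norm_a)
  if (is.null(genes) || !identical(genes, names(te_norm_b))) {
    stop("normalized TE vectors must be named over the same genes")
  }
  delta <- te_norm_a - te_norm_b
  flag <- rep("ns", length(genes))
  flag[delta > delta_threshold] <- "up_A"
  flag[-delta > delta_threshold] <- "up_B"
  data.frame(gene_id = genes, te_norm_a = unname(te_norm_a),
             te_norm_b = unname(te_norm_b), delta = unname(delta),
             flag = flag, stringsAsFactors = FALSE)
}

#' TE analysis across both conditions
#'
#' Computes per-condition TE over eligible genes, restricts to the common
#' eligible gene set, normalizes within each condition over that set, and
#' calls differential TE.
#'
#' @param ab An `AbundanceTable` with the four-library design.
#' @param min_fpkm Cytosolic eligibility threshold.
#' @param method Normalization method, see [normalize_te()].
#' @param delta_threshold See [call_differential_te()].
#' @return List with `te_a`, `te_b` (full eligible TE vectors),
#'   `n_eligible_a`, `n_eligible_b`, `n_common`, and `calls` (the
#'   common-gene table with TE and normalized TE per condition).
#' @export
te_analysis <- function(ab, min_fpkm = 1, method = "rank",
                        delta_threshold = 0.5) {
  gf <- gene_fpkm(ab)
  te_a <- compute_te(
    stats::setNames(gf[, library_id(ab, "A", "cytosolic")], rownames(gf)),
    stats::setNames(gf[, library_id(ab, "A", "ribosome")], rownames(gf)),
    min_fpkm)
  te_b <- compute_te(
    stats::setNames(gf[, library_id(ab, "B", "cytosolic")], rownames(gf)),
    stats::setNames(gf[, library_id(ab, "B", "ribosome")], rownames(gf)),
    min_fpkm)
  common <- intersect(names(te_a), names(te_b))
  na <- normalize_te(te_a[common], method)
  nb <- normalize_te(te_b[common], method)
  calls <- call_differential_te(na, nb, delta_threshold)
  calls$te_a <- unname(te_a[common])
  calls$te_b <- unname(te_b[common])
  list(te_a = te_a, te_b = te_b,
       n_eligible_a = length(te_a), n_eligible_b = length(te_b),
       n_common = length(common), calls = calls)
}
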