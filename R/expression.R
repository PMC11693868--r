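#' Compute FPKM from counts
#'
#' `fpkm = counts * 1e9 / (length * total_mapped_reads)`.
#'
#' @param counts Transcript-by-library count matrix.
#' @param lengths Per-transcript length in nt (named or in row order).
#' @param totals Per-library total mapped reads (named or in column order).
#' @return FPKM matrix of the same shape.
#' @export
compute_fpkm <- function(counts, lengths, totals) {
  stopifnot(is.matrix(counts))
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (!is.null(names(totals)) && !is.null(colnames(counts))) {
    totals <- totals[colnames(counts)]
  }
  if (length(lengths) != nrow(counts) || length(totals) != ncol(counts)) {
    stop("shape mismatch between counts, lengths and totals")
  }
  if (any(lengths < 1)) stop("lengths must be >= 1")
  if (any(totals < 1)) stop("totals must be >= 1")
  sweep(counts / lengths, 2, totals, "/") * 1e9
}

#' Two-sided Fisher exact test of one gene against the library totals
#'
#' Exact p-value for the 2x2 table `[[x1, t1 - x1], [x2, t2 - x2]]`,
#' conditioning on the margins: the sum of hypergeometric point
#' probabilities not exceeding that of the observed table (the convention
#' of `stats::fisher.test`), computed directly over the support so that
#' genome-scale margins stay fast.
#'
#' @param x1,x2 Gene counts in the two libraries (rounded to integers).
#' @param t1,t2 Library totals.
#' @return Two-sided p-value.
#' @export
fisher_gene_p <- function(x1, t1, x2, t2) {
  x1 <- round(x1); x2 <- round(x2); t1 <- round(t1); t2 <- round(t2)
  k <- x1 + x2
  lo <- max(0, k - t2)
  hi <- min(k, t1)
  supp <- lo:hi
  d <- stats::dhyper(supp, t1, t2, k)
  # relative slack for ties, as in fisher.test
  min(1, sum(d[d <= d[x1 - lo + 1] * (1 + 1e-7)]))
}

#' Replicate-free differential calling between two libraries
#'
#' One gene is called differential when all three criteria hold:
#' `|log2(fold change)| >= min_abs_log2fc`, FPKM at least `min_fpkm` in at
#' least one condition, and Benjamini-Hochberg adjusted p-value at most
#' `max_p_adj`. With a single library per condition the p-value comes from a
#' two-sided Fisher exact test of the 2x2 table
#' (gene count, library total - gene count) across the two libraries; the
#' BH family is the set of genes passing the expression filter. The
#' pseudocount enters the fold change only, never the test.
#'
#' @param counts_a,counts_b Named per-gene counts in conditions A and B.
#' @param fpkm_a,fpkm_b Named per-gene FPKM in conditions A and B.
#' @param total_a,total_b Library totals (mapped reads).
#' @param min_abs_log2fc,min_fpkm,max_p_adj Calling thresholds (defaults: 1,
#'   1, 0.001).
#' @param pseudocount FPKM pseudocount for the fold change (default 0.25).
#' @return data.frame with columns `gene_id`, `count_a`, `count_b`,
#'   `fpkm_a`, `fpkm_b`, `log2fc`, `tested`, `p_raw`, `p_adj`, `flag`
#'   (`"up_A"`, `"up_B"`, `"ns"`). `log2fc` is B over A, so `up_B` means
#'   higher in condition B.
#' @export
call_differential <- function(counts_a, counts_b, fpkm_a, fpkm_b,
                              total_a, total_b,
                              min_abs_log2fc = 1, min_fpkm = 1,
                              max_p_adj = 0.001, pseudocount = 0.25) {
  if (total_a < 1 || total_b < 1) stop("zero library total")
  genes <- names(counts_a)
  if (is.null(genes) ||
      !identical(genes, names(counts_b)) ||
      !identical(genes, names(fpkm_a)) ||
      !identical(genes, names(fpkm_b))) {
    stop("inputs must be named vectors over the same genes, same order")
  }
  log2fc <- log2((fpkm_b + pseudocount) / (fpkm_a + pseudocount))
  tested <- fpkm_a >= min_fpkm | fpkm_b >= min_fpkm
  p_raw <- rep(NA_real_, length(genes))
  p_raw[tested] <- vapply(which(tested), function(i) {
    fisher_gene_p(counts_a[i], total_a, counts_b[i], total_b)
  }, numeric(1))
  p_adj <- rep(NA_real_, length(genes))
  p_adj[tested] <- stats::p.adjust(p_raw[tested], method = "BH")
  flag <- rep("ns", length(genes))
  sig <- tested & !is.na(p_adj) & p_adj <= max_p_adj &
    abs(log2fc) >= min_abs_log2fc
  flag[sig & log2fc > 0] <- "up_B"
  flag[sig & log2fc < 0] <- "up_A"
  data.frame(gene_id = genes,
             count_a = unname(counts_a), count_b = unname(counts_b),
             fpkm_a = unname(fpkm_a), fpkm_b = unname(fpkm_b),
             log2fc = unname(log2fc), tested = unname(tested),
             p_raw = unname(p_raw), p_adj = unname(p_adj), flag = flag,
             stringsAsFactors = FALSE)
}

#' DEG and DTG calling from an abundance table
#'
#' Runs [call_differential()] twice: condition A vs B on the cytosolic
#' libraries (transcriptome; DEGs) and on the ribosome-associated libraries
#' (translatome; DTGs), at gene level (counts and FPKM summed over
#' isoforms).
#'
#' @param ab An `AbundanceTable` with the four-library design.
#' @param ... Thresholds passed to [call_differential()].
#' @return List with data.frames `transcriptome` and `translatome`.
#' @export
call_deg_dtg <- function(ab, ...) {
  gc <- gene_counts(ab)
  gf <- gene_fpkm(ab)
  lib <- ab$libraries
  one <- function(fraction) {
    la <- library_id(ab, "A", fraction)
    lb <- library_id(ab, "B", fraction)
    call_differential(
      stats::setNames(gc[, la], rownames(gc)),
      stats::setNames(gc[, lb], rownames(gc)),
      stats::setNames(gf[, la], rownames(gf)),
      stats::setNames(gf[, lb], rownames(gf)),
      lib[la, "total_mapped_reads"], lib[lb, "total_mapped_reads"], ...)
  }
  list(transcriptome = one("cytosolic"), translatome = one("ribosome"))
}

#' Overlap between two gene call sets
#'
#' @param deg,dtg Character vectors of gene ids (e.g. DEGs and DTGs).
#' @return List with `n_deg`, `n_dtg`, `n_shared`, `frac_of_deg`,
#'   `frac_of_dtg`.
#' @export
overlap_calls <- function(deg, dtg) {
  deg <- unique(deg)
  dtg <- unique(dtg)
  shared <- length(intersect(deg, dtg))
  list(n_deg = length(deg), n_dtg = length(dtg), n_shared = shared,
       frac_of_deg = if (length(deg) > 0) shared / length(deg) else NA_real_,
       frac_of_dtg = if (length(dtg) > 0) shared / length(dtg) else NA_real_)
}
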