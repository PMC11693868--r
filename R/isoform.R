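#' Per-isoform composition proportions (CP)
#'
#' CP of isoform i is its share of the gene total in one fraction,
#' `count_i / sum_j count_j`, computed over the isoforms passing the
#' per-transcript expression filter (FPKM >= `min_tx_fpkm` in that
#' fraction) and renormalized after filtering.
#'
#' @param ab An `AbundanceTable`.
#' @param gene_id Gene to profile.
#' @param condition `"A"` or `"B"`.
#' @param fraction `"cytosolic"` or `"ribosome"`.
#' @param min_tx_fpkm Per-transcript expression filter (default 1).
#' @param units `"count"` (default) or `"fpkm"` proportions.
#' @return Named CP vector over expressed isoforms (empty when none pass).
#' @export
isoform_proportions <- function(ab, gene_id, condition, fraction,
                                min_tx_fpkm = 1, units = c("count", "fpkm")) {
  units <- match.arg(units)
  lib <- library_id(ab, condition, fraction)
  txs <- names(ab$tx2gene)[ab$tx2gene == gene_id]
  if (length(txs) == 0) stop("unknown gene: ", gene_id)
  keep <- txs[ab$fpkm[txs, lib] >= min_tx_fpkm]
  if (length(keep) == 0) return(stats::setNames(numeric(0), character(0)))
  x <- if (units == "count") ab$counts[keep, lib] else ab$fpkm[keep, lib]
  x <- stats::setNames(as.numeric(x), keep)
  if (sum(x) <= 0) return(stats::setNames(numeric(0), character(0)))
  x / sum(x)
}

#' Chi-square test for ribosome-selective isoform usage
#'
#' Tests homogeneity of the isoform composition between the cytosolic and
#' ribosome fractions of one gene via a Pearson chi-square on the 2-by-k
#' count table, with two small-sample modifications: a pseudocount added to
#' every cell, and isoforms whose expected cell count falls below
#' `min_expected` merged (smallest share first) into a single "other" bin
#' until all expectations pass or only two bins remain. With
#' `pseudocount = 0` and `min_expected = 0` this is the unmodified Pearson
#' test.
#'
#' @param counts_cyto,counts_ribo Named per-isoform estimated counts over
#'   the same isoforms (k >= 2).
#' @param min_expected Minimum expected cell count before merging
#'   (default 5).
#' @param pseudocount Added to every cell (default 0.5).
#' @return List with `stat`, `df` (= bins - 1), `p`, `k_input`, `k_used`,
#'   `merged` (ids absorbed into the "other" bin).
#' @export
selective_usage_test <- function(counts_cyto, counts_ribo,
                                 min_expected = 5, pseudocount = 0.5) {
  k <- length(counts_cyto)
  if (length(counts_ribo) != k ||
      !identical(names(counts_cyto), names(counts_ribo))) {
    stop("counts_cyto and counts_ribo must cover the same isoforms")
  }
  if (k < 2) {
    return(list(stat = NA_real_, df = NA_integer_, p = NA_real_,
                k_input = k, k_used = k, merged = character(0)))
  }
  tab <- rbind(cyto = as.numeric(counts_cyto),
               ribo = as.numeric(counts_ribo)) + pseudocount
  colnames(tab) <- names(counts_cyto)
  merged <- character(0)
  other <- NA_integer_
  repeat {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (min(expected) >= min_expected || ncol(tab) <= 2) break
    cs <- colSums(tab)
    if (is.na(other)) {
      o <- order(cs)[1:2]
      merged <- c(merged, colnames(tab)[o])
      newcol <- tab[, o[1]] + tab[, o[2]]
      tab <- cbind(tab[, -o, drop = FALSE], other = newcol)
    } else {
      cs[other] <- Inf
      j <- which.min(cs)
      merged <- c(merged, colnames(tab)[j])
      tab[, other] <- tab[, other] + tab[, j]
      tab <- tab[, -j, drop = FALSE]
    }
    other <- which(colnames(tab) == "other")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1L
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       k_input = k, k_used = ncol(tab), merged = merged)
}

#' BH adjustment and selection flags for the isoform-usage tests
#'
#' The multiple-testing family is the set of testable genes (>= 2 expressed
#' isoforms) of one condition.
#'
#' @param p_raw Named per-gene raw p-values.
#' @param alpha Selection threshold on the q-value (default 0.05).
#' @return data.frame with `gene_id`, `p_raw`, `q_value`, `selected`.
#' @export
adjust_selection_pvalues <- function(p_raw, alpha = 0.05) {
  if (length(p_raw) == 0) {
    return(data.frame(gene_id = character(0), p_raw = numeric(0),
                      q_value = numeric(0), selected = logical(0)))
  }
  q <- stats::p.adjust(p_raw, method = "BH")
  data.frame(gene_id = names(p_raw), p_raw = unname(p_raw),
             q_value = unname(q), selected = unname(q <= alpha),
             stringsAsFactors = FALSE)
}

#' Diff_CP: ribosome-selection score per isoform
#'
#' `Diff_CP_i = CP_ribo_i - CP_cyto_i` over the union of the two fractions'
#' expressed isoforms (absent = 0). Positive values mark isoforms
#' preferentially selected by ribosomes; the scores of one gene sum to 0.
#'
#' @param cp_cyto,cp_ribo Named CP vectors (each sums to 1 when non-empty).
#' @return Named Diff_CP vector over the union of isoforms.
#' @export
diff_cp <- function(cp_cyto, cp_ribo) {
  ids <- sort(union(names(cp_cyto), names(cp_ribo)))
  full <- function(cp) {
    out <- stats::setNames(rep(0, length(ids)), ids)
    out[names(cp)] <- cp
    out
  }
  full(cp_ribo) - full(cp_cyto)
}

#' Extreme isoforms of a gene
#'
#' The maximally positively selected transcript (argmax Diff_CP) and the
#' maximally negatively selected transcript (argmin). Ties are broken by
#' higher cytosolic CP, then lexicographic transcript id. An all-zero score
#' vector is flagged `no_selection` (the pair then follows the tie rules).
#'
#' @param dcp Named Diff_CP vector (k >= 2).
#' @param cp_cyto Optional named cytosolic CP vector for tie-breaking.
#' @return List with `max_pos_tx`, `max_neg_tx`, `no_selection`.
#' @export
extreme_isoforms <- function(dcp, cp_cyto = NULL) {
  if (length(dcp) < 2) stop("extreme isoforms need k >= 2")
  ids <- names(dcp)
  cpc <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(cp_cyto)) cpc[names(cp_cyto)] <- cp_cyto
  pos <- ids[order(-dcp, -cpc, ids)][1]
  neg <- ids[order(dcp, -cpc, ids)][1]
  list(max_pos_tx = pos, max_neg_tx = neg,
       no_selection = all(abs(dcp) < 1e-12))
}

intervals_equal <- function(a, b) {
  nrow(a) == nrow(b) && (nrow(a) == 0 || all(a == b))
}

#' Structural elements differing between two isoforms
#'
#' Compares the normalized genomic interval sets of the 5'UTR, 3'UTR and
#' CDS between two transcripts of the same gene. When exactly one of the
#' pair lacks a CDS annotation, the comparison is undefined element-wise and
#' every element present in either transcript is reported.
#'
#' @param tx_a,tx_b Transcript ids (same gene).
#' @param catalog A `TranscriptCatalog`.
#' @return Character vector, subset of `c("utr5", "utr3", "cds")`.
#' @export
compare_structural_elements <- function(tx_a, tx_b, catalog) {
  tx <- catalog$transcripts
  if (!tx_a %in% tx$transcript_id) stop("unknown transcript: ", tx_a)
  if (!tx_b %in% tx$transcript_id) stop("unknown transcript: ", tx_b)
  if (tx[tx_a, "gene_id"] != tx[tx_b, "gene_id"]) {
    stop("transcripts belong to different genes: ", tx_a, ", ", tx_b)
  }
  elements <- c("utr5", "utr3", "cds")
  ia <- lapply(elements, function(e)
    normalize_intervals(feature_intervals(catalog, tx_a, e)))
  ib <- lapply(elements, function(e)
    normalize_intervals(feature_intervals(catalog, tx_b, e)))
  names(ia) <- names(ib) <- elements
  coding_a <- nrow(ia$cds) > 0
  coding_b <- nrow(ib$cds) > 0
  if (xor(coding_a, coding_b)) {
    present <- vapply(elements, function(e)
      nrow(ia[[e]]) > 0 || nrow(ib[[e]]) > 0, logical(1))
    return(elements[present])
  }
  differs <- vapply(elements, function(e)
    !intervals_equal(ia[[e]], ib[[e]]), logical(1))
  elements[differs]
}

#' Multi-isoform usage statistics
#'
#' Fraction of genes using at least two expressed isoforms in one library.
#'
#' @param ab An `AbundanceTable`.
#' @param condition `"A"` or `"B"`.
#' @param fraction `"cytosolic"` or `"ribosome"`.
#' @param min_tx_fpkm Per-transcript expression filter.
#' @return List with `n_genes_ge2_expressed`, `n_genes_total`, `proportion`.
#' @export
multi_isoform_stats <- function(ab, condition, fraction, min_tx_fpkm = 1) {
  lib <- library_id(ab, condition, fraction)
  expressed <- ab$fpkm[, lib] >= min_tx_fpkm
  per_gene <- tapply(expressed, ab$tx2gene, sum)
  n_total <- length(per_gene)
  n_ge2 <- sum(per_gene >= 2)
  list(n_genes_ge2_expressed = n_ge2, n_genes_total = n_total,
       proportion = if (n_total > 0) n_ge2 / n_total else NA_real_)
}

#' Two-sample proportion test
#'
#' Two-sided chi-square test of equal proportions with Yates continuity
#' correction (the classic prop-test convention).
#'
#' @param x1,n1,x2,n2 Successes and totals of the two samples.
#' @return p-value in [0, 1].
#' @export
proportion_test <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("sample sizes must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("successes must satisfy 0 <= x <= n")
  }
  suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE)$p.value)
}

#' Dominant transcript of a gene
#'
#' The isoform expressed at a considerably higher level than the others:
#' dominant when its CP reaches `cp_min` and is at least `ratio_min` times
#' the runner-up's. Single-isoform genes are dominant by definition.
#'
#' @param cp Named per-isoform CP vector (k >= 1).
#' @param cp_min Minimum CP of the top isoform (default 0.5).
#' @param ratio_min Minimum top/runner-up ratio (default 2).
#' @return The dominant transcript id, or `NA_character_` when none
#'   qualifies.
#' @export
call_dominant_transcript <- function(cp, cp_min = 0.5, ratio_min = 2) {
  if (length(cp) == 0) stop("empty proportion vector")
  if (length(cp) == 1) return(names(cp))
  ord <- order(-cp, names(cp))
  top <- cp[ord[1]]
  second <- cp[ord[2]]
  if (top >= cp_min && top >= ratio_min * second) names(cp)[ord[1]]
  else NA_character_
}

#' Dominant-transcript switch status
#'
#' @param dom_cyto,dom_ribo Dominant transcript ids per fraction
#'   (`NA` = none).
#' @return `"unchanged"`, `"switched"`, or `"undefined"`.
#' @export
detect_dominant_switch <- function(dom_cyto, dom_ribo) {
  if (is.na(dom_cyto) || is.na(dom_ribo)) return("undefined")
  if (dom_cyto == dom_ribo) "unchanged" else "switched"
}

#' Full per-gene isoform-selection analysis for one condition
#'
#' For every gene: composition proportions per fraction, the modified
#' chi-square selective-usage test on the union of expressed isoforms,
#' BH-adjusted q-values over the testable family, Diff_CP scores, the
#' extreme (max positive / max negative) isoform pair and its structural
#' difference, and dominant-transcript calls per fraction with switch
#' status.
#'
#' @param ab An `AbundanceTable`.
#' @param condition `"A"` or `"B"`.
#' @param catalog Optional `TranscriptCatalog` enabling the structural
#'   comparison of the extreme pair.
#' @param min_tx_fpkm Per-transcript expression filter (default 1).
#' @param min_expected,pseudocount See [selective_usage_test()].
#' @param alpha Selection q-value threshold (default 0.05).
#' @param dominant_cp,dominant_ratio See [call_dominant_transcript()].
#' @param units CP units, see [isoform_proportions()].
#' @return List with `genes` (one row per gene), `isoforms` (one row per
#'   isoform with CP and Diff_CP), and `metadata` (the parameter set, for
#'   output provenance).
#' @export
isoform_selection_analysis <- function(ab, condition, catalog = NULL,
                                       min_tx_fpkm = 1, min_expected = 5,
                                       pseudocount = 0.5, alpha = 0.05,
                                       dominant_cp = 0.5,
                                       dominant_ratio = 2,
                                       units = "count") {
  lib_c <- library_id(ab, condition, "cytosolic")
  lib_r <- library_id(ab, condition, "ribosome")
  genes <- sort(unique(ab$tx2gene))
  tx_by_gene <- split(names(ab$tx2gene), ab$tx2gene)
  rows <- vector("list", length(genes))
  iso_rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    cpc <- isoform_proportions(ab, g, condition, "cytosolic",
                               min_tx_fpkm, units)
    cpr <- isoform_proportions(ab, g, condition, "ribosome",
                               min_tx_fpkm, units)
    u <- sort(union(names(cpc), names(cpr)))
    k <- length(u)
    testable <- k >= 2
    test <- if (testable) {
      selective_usage_test(
        stats::setNames(ab$counts[u, lib_c], u),
        stats::setNames(ab$counts[u, lib_r], u),
        min_expected = min_expected, pseudocount = pseudocount)
    } else {
      list(stat = NA_real_, df = NA_integer_, p = NA_real_)
    }
    dcp <- if (k > 0) diff_cp(cpc, cpr) else
      stats::setNames(numeric(0), character(0))
    ext <- if (k >= 2) extreme_isoforms(dcp, cpc) else
      list(max_pos_tx = NA_character_, max_neg_tx = NA_character_,
           no_selection = TRUE)
    structural <- NA_character_
    if (!is.null(catalog) && k >= 2 && !is.na(ext$max_pos_tx) &&
        ext$max_pos_tx != ext$max_neg_tx &&
        all(c(ext$max_pos_tx, ext$max_neg_tx) %in%
              catalog$transcripts$transcript_id)) {
      d <- compare_structural_elements(ext$max_pos_tx, ext$max_neg_tx,
                                       catalog)
      structural <- if (length(d) == 0) "" else paste(d, collapse = ",")
    }
    dom_c <- if (length(cpc) > 0) {
      call_dominant_transcript(cpc, dominant_cp, dominant_ratio)
    } else NA_character_
    dom_r <- if (length(cpr) > 0) {
      call_dominant_transcript(cpr, dominant_cp, dominant_ratio)
    } else NA_character_
    rows[[gi]] <- data.frame(
      gene_id = g, n_isoforms = length(tx_by_gene[[g]]),
      n_expressed_union = k, testable = testable,
      chi2_stat = test$stat, df = test$df, p_raw = test$p,
      max_pos_tx = ext$max_pos_tx, max_neg_tx = ext$max_neg_tx,
      no_selection = ext$no_selection, structural_diff = structural,
      dominant_cyto = dom_c, dominant_ribo = dom_r,
      dominant_status = detect_dominant_switch(dom_c, dom_r),
      stringsAsFactors = FALSE)
    if (k > 0) {
      full_c <- stats::setNames(rep(0, k), u)
      full_c[names(cpc)] <- cpc
      full_r <- stats::setNames(rep(0, k), u)
      full_r[names(cpr)] <- cpr
      iso_rows[[gi]] <- data.frame(
        gene_id = g, transcript_id = u,
        cp_cyto = unname(full_c), cp_ribo = unname(full_r),
        diff_cp = unname(dcp[u]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  res$selected <- FALSE
  fam <- res$testable & !is.na(res$p_raw)
  if (any(fam)) {
    adj <- adjust_selection_pvalues(
      stats::setNames(res$p_raw[fam], res$gene_id[fam]), alpha = alpha)
    res$q_value[fam] <- adj$q_value
    res$selected[fam] <- adj$selected
  }
  list(genes = res,
       isoforms = do.call(rbind, iso_rows[!vapply(iso_rows, is.null,
                                                  logical(1))]),
       metadata = list(condition = condition, min_tx_fpkm = min_tx_fpkm,
                       min_expected = min_expected,
                       pseudocount = pseudocount, alpha = alpha,
                       dominant_cp = dominant_cp,
                       dominant_ratio = dominant_ratio, units = units,
                       test = "pearson-chi2+pseudocount+merge"))
}
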