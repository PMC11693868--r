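#' Simulation parameters
#'
#' Defines the synthetic experiment: a multi-isoform transcript catalog and
#' negative-binomial transcript counts for the four libraries
#' (two conditions x two fractions), with planted differential expression,
#' differential translational efficiency, ribosome-selective isoform usage,
#' and dominant-transcript switches.
#'
#' Default isoform-count weights give a mean of ~1.9 isoforms per gene, the
#' multi-isoform density typical of an assembled fly transcriptome. The
#' default dispersion is near-Poisson because the emulated design has no
#' biological replicates: library-to-library noise within a condition is
#' technical; raise `nb_dispersion` to study biological overdispersion.
#'
#' @param n_genes Number of genes.
#' @param isoform_count_weights Probability weights over 1..5 isoforms/gene.
#' @param structure_vary_weights Named weights (`utr5`, `utr3`, `cds`) for
#'   which structural element distinguishes the isoforms of a multi-isoform
#'   gene.
#' @param mean_expression_log2,sd_expression_log2 Log2-normal gene baseline
#'   expression.
#' @param te_baseline_log2_sd Spread (log2) of the per-gene intrinsic
#'   ribosome/cytosolic abundance ratio, shared between conditions.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param frac_de_genes,de_log2fc Fraction of genes with differential
#'   expression between conditions and the planted |log2 fold change|.
#' @param frac_te_shift_genes,te_shift_log2 Fraction of genes whose
#'   ribosome-fraction abundance in condition B is shifted by
#'   `2^(+/- te_shift_log2)`.
#' @param frac_selection_genes,selection_cp_shift Fraction of multi-isoform
#'   genes with ribosome-selective isoform usage, and the composition
#'   proportion added to one isoform in the ribosome fraction
#'   (in (0, 0.5]).
#' @param frac_dominant_switch Fraction of multi-isoform genes whose top two
#'   ribosome-fraction isoform proportions are swapped, moving the dominant
#'   transcript.
#' @param dirichlet_alpha Concentration of the per-gene Dirichlet draw of
#'   cytosolic isoform proportions.
#' @param library_depth Expected total counts per library.
#' @param replicates Libraries per condition x fraction (default 1, the
#'   replicate-free design).
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A validated list of class `SimulationParams`.
#' @export
simulation_params <- function(n_genes = 200,
                              isoform_count_weights =
                                c(0.45, 0.30, 0.15, 0.07, 0.03),
                              structure_vary_weights =
                                c(utr5 = 0.4, utr3 = 0.4, cds = 0.2),
                              mean_expression_log2 = 8,
                              sd_expression_log2 = 1.5,
                              te_baseline_log2_sd = 1,
                              nb_dispersion = 1e-4,
                              frac_de_genes = 0.1,
                              de_log2fc = 2,
                              frac_te_shift_genes = 0.1,
                              te_shift_log2 = 3,
                              frac_selection_genes = 0.1,
                              selection_cp_shift = 0.3,
                              frac_dominant_switch = 0.05,
                              dirichlet_alpha = 1,
                              library_depth = 1e6,
                              replicates = 1,
                              seed = 1) {
  p <- list(n_genes = n_genes,
            isoform_count_weights = isoform_count_weights,
            structure_vary_weights = structure_vary_weights,
            mean_expression_log2 = mean_expression_log2,
            sd_expression_log2 = sd_expression_log2,
            te_baseline_log2_sd = te_baseline_log2_sd,
            nb_dispersion = nb_dispersion,
            frac_de_genes = frac_de_genes, de_log2fc = de_log2fc,
            frac_te_shift_genes = frac_te_shift_genes,
            te_shift_log2 = te_shift_log2,
            frac_selection_genes = frac_selection_genes,
            selection_cp_shift = selection_cp_shift,
            frac_dominant_switch = frac_dominant_switch,
            dirichlet_alpha = dirichlet_alpha,
            library_depth = library_depth,
            replicates = replicates, seed = seed)
  if (p$n_genes < 1) stop("n_genes must be >= 1")
  for (f in c("frac_de_genes", "frac_te_shift_genes",
              "frac_selection_genes", "frac_dominant_switch")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0,1]")
  }
  if (p$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (p$selection_cp_shift <= 0 || p$selection_cp_shift > 0.5) {
    stop("selection_cp_shift must be in (0, 0.5]")
  }
  if (any(p$isoform_count_weights < 0) ||
      sum(p$isoform_count_weights) <= 0) {
    stop("isoform_count_weights must be nonnegative with positive sum")
  }
  if (p$library_depth < 1) stop("library_depth must be >= 1")
  if (p$replicates < 1) stop("replicates must be >= 1")
  structure(p, class = "SimulationParams")
}

#' Generate a synthetic transcript catalog
#'
#' Genes live on one pseudo-chromosome, alternating strands. All isoforms of
#' a gene share a CDS core; multi-isoform genes vary in exactly one recorded
#' structural element: the 5'UTR end (shifted transcript start), the 3'UTR
#' end, or the CDS (a distinct internal coding exon), so structural
#' comparisons downstream have known answers. The per-gene varied element is
#' attached as `attr(catalog, "structure_truth")`.
#'
#' @param params A [simulation_params()] object.
#' @return A `TranscriptCatalog`.
#' @export
generate_catalog <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  withr::local_seed(params$seed)
  n <- params$n_genes
  ks <- sample(seq_along(params$isoform_count_weights), n, replace = TRUE,
               prob = params$isoform_count_weights)
  varied <- rep("none", n)
  multi <- ks >= 2
  if (any(multi)) {
    w <- params$structure_vary_weights
    varied[multi] <- sample(names(w), sum(multi), replace = TRUE, prob = w)
  }
  gene_of_tx <- rep(seq_len(n), ks)
  j <- unlist(lapply(ks, seq_len), use.names = FALSE)
  gid <- sprintf("G%05d", gene_of_tx)
  tid <- sprintf("%s.T%d", gid, j)
  strand <- ifelse(gene_of_tx %% 2 == 1, "+", "-")
  off <- (gene_of_tx - 1) * 10000
  vtx <- varied[gene_of_tx]
  # the transcript 5'/3' variation lands on the genomic left/right end
  # according to strand; the CDS variation is a distinct internal coding exon
  left_var <- ifelse((vtx == "utr5" & strand == "+") |
                       (vtx == "utr3" & strand == "-"), j - 1, 0)
  right_var <- ifelse((vtx == "utr3" & strand == "+") |
                        (vtx == "utr5" & strand == "-"), j - 1, 0)
  left <- off + 100 - 25 * left_var
  right <- off + 1800 + 40 * right_var
  has_int <- vtx == "cds" & j >= 2
  int_s <- off + 700
  int_e <- off + 720 + 20 * pmax(j - 2, 0)
  feat <- function(type, s, e, sel = rep(TRUE, length(tid))) {
    data.frame(transcript_id = tid[sel], type = rep_len(type, sum(sel)),
               start = s[sel], end = e[sel], stringsAsFactors = FALSE)
  }
  features <- rbind(
    feat("exon", left, off + 600),
    feat("exon", int_s, int_e, has_int),
    feat("exon", off + 1000, right),
    feat("cds", off + 300, off + 600),
    feat("cds", int_s, int_e, has_int),
    feat("cds", off + 1000, off + 1400),
    feat("utr5", ifelse(strand == "+", left, off + 1400),
         ifelse(strand == "+", off + 300, right)),
    feat("utr3", ifelse(strand == "+", off + 1400, left),
         ifelse(strand == "+", right, off + 300)))
  catalog <- transcript_catalog(
    data.frame(transcript_id = tid, gene_id = gid, chrom = "chrS",
               strand = strand, stringsAsFactors = FALSE),
    features)
  attr(catalog, "structure_truth") <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    n_isoforms = ks, varied_element = varied,
    stringsAsFactors = FALSE)
  catalog
}

#' Shift one isoform's composition proportion
#'
#' Adds `shift` to the target isoform (capped so it stays <= 1) and rescales
#' the others proportionally, so the result still sums to 1. This is the
#' planting rule for ribosome-selective isoform usage: e.g. cytosolic
#' proportions (0.5, 0.5) with shift 0.3 on the first isoform give ribosome
#' proportions (0.8, 0.2).
#'
#' @param cp Proportion vector summing to 1.
#' @param shift Amount added to `cp[target]`.
#' @param target Index of the favoured isoform.
#' @return Shifted proportion vector summing to 1.
#' @export
plant_cp_shift <- function(cp, shift, target) {
  stopifnot(abs(sum(cp) - 1) < 1e-8, target >= 1, target <= length(cp))
  s <- min(shift, 1 - cp[target])
  new_t <- cp[target] + s
  out <- cp
  if (cp[target] < 1) {
    out[-target] <- cp[-target] * (1 - new_t) / (1 - cp[target])
  }
  out[target] <- new_t
  out
}

#' Simulate four-library negative-binomial counts with planted effects
#'
#' Per gene, baseline expression is log-normal and an intrinsic
#' ribosome/cytosolic ratio (shared between conditions) is log-normal.
#' Differential-expression genes are scaled by `2^(+/- de_log2fc)` in
#' condition B; TE-shifted genes additionally scale their condition-B
#' ribosome fraction by `2^(+/- te_shift_log2)`. Cytosolic isoform
#' proportions are Dirichlet; ribosome-fraction proportions are shifted for
#' selected genes ([plant_cp_shift()]) and top-two-swapped for planted
#' dominant switches. Transcript counts are negative binomial around
#' depth-scaled expectations; FPKM follows from counts, lengths and depth.
#'
#' @param catalog A `TranscriptCatalog` (typically [generate_catalog()]).
#' @param params A [simulation_params()] object.
#' @return List with elements `abundance` (an `AbundanceTable`), `truth`
#'   (list of per-gene and per-isoform ground-truth data.frames) and
#'   `lengths` (named transcript length vector).
#' @export
simulate_counts <- function(catalog, params) {
  stopifnot(inherits(params, "SimulationParams"))
  if (params$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  withr::local_seed(as.integer(params$seed) + 1L)
  g2t <- gene_transcripts(catalog)
  gene_ids <- names(g2t)
  n <- length(gene_ids)
  ks <- lengths(g2t)
  mu <- 2 ^ stats::rnorm(n, params$mean_expression_log2,
                         params$sd_expression_log2)
  tau <- 2 ^ stats::rnorm(n, 0, params$te_baseline_log2_sd)
  is_de <- stats::runif(n) < params$frac_de_genes
  de_dir <- ifelse(is_de, sample(c(-1, 1), n, replace = TRUE), 0L)
  is_te <- stats::runif(n) < params$frac_te_shift_genes
  te_dir <- ifelse(is_te, sample(c(-1, 1), n, replace = TRUE), 0L)
  is_sel <- ks >= 2 & stats::runif(n) < params$frac_selection_genes
  is_switch <- ks >= 2 & stats::runif(n) < params$frac_dominant_switch

  cp_cyto <- vector("list", n)
  cp_ribo <- vector("list", n)
  for (i in seq_len(n)) {
    k <- ks[i]
    g <- stats::rgamma(k, shape = params$dirichlet_alpha)
    cpc <- g / sum(g)
    cpr <- cpc
    if (is_sel[i]) {
      cpr <- plant_cp_shift(cpr, params$selection_cp_shift, sample(k, 1))
    }
    if (is_switch[i]) {
      ord <- order(cpr, decreasing = TRUE)
      cpr[ord[1:2]] <- cpr[ord[2:1]]
    }
    cp_cyto[[i]] <- cpc
    cp_ribo[[i]] <- cpr
  }

  lib_tab <- do.call(rbind, lapply(c("A", "B"), function(cond) {
    do.call(rbind, lapply(c("cytosolic", "ribosome"), function(fr) {
      do.call(rbind, lapply(seq_len(params$replicates), function(r) {
        id <- paste0(cond, "_", if (fr == "cytosolic") "cyto" else "ribo")
        if (params$replicates > 1) id <- paste0(id, "_rep", r)
        library_spec(id, cond, fr, params$library_depth)
      }))
    }))
  }))

  tx_ids <- unlist(g2t, use.names = FALSE)
  tx_gene <- rep(gene_ids, ks)
  lengths <- catalog$transcripts[tx_ids, "length"]
  names(lengths) <- tx_ids

  counts <- matrix(0, nrow = length(tx_ids), ncol = nrow(lib_tab),
                   dimnames = list(tx_ids, lib_tab$library_id))
  fpkm <- counts
  for (li in seq_len(nrow(lib_tab))) {
    cond <- lib_tab$condition[li]
    fr <- lib_tab$fraction[li]
    m <- mu
    if (cond == "B") m <- m * 2 ^ (de_dir * params$de_log2fc)
    if (fr == "ribosome") {
      m <- m * tau
      if (cond == "B") m <- m * 2 ^ (te_dir * params$te_shift_log2)
    }
    cp <- if (fr == "ribosome") cp_ribo else cp_cyto
    e_tx <- unlist(lapply(seq_len(n), function(i) m[i] * cp[[i]]),
                   use.names = FALSE)
    e_tx <- params$library_depth * e_tx / sum(e_tx)
    counts[, li] <- stats::rnbinom(length(e_tx), mu = e_tx,
                                   size = 1 / params$nb_dispersion)
    fpkm[, li] <- counts[, li] * 1e9 /
      (lengths * lib_tab$total_mapped_reads[li])
  }

  dom <- function(cp, txs) {
    d <- call_dominant_transcript(stats::setNames(cp, txs))
    if (is.na(d)) NA_character_ else d
  }
  truth_genes <- data.frame(
    gene_id = gene_ids, n_isoforms = as.integer(ks),
    baseline_expression = mu, intrinsic_te = tau,
    is_de = is_de, de_direction = as.integer(de_dir),
    is_te_shifted = is_te, te_direction = as.integer(te_dir),
    is_selected = is_sel, is_switch_planted = is_switch,
    dominant_cyto = vapply(seq_len(n),
                           function(i) dom(cp_cyto[[i]], g2t[[i]]),
                           character(1)),
    dominant_ribo = vapply(seq_len(n),
                           function(i) dom(cp_ribo[[i]], g2t[[i]]),
                           character(1)),
    stringsAsFactors = FALSE)
  st <- attr(catalog, "structure_truth")
  if (!is.null(st)) {
    truth_genes$varied_element <-
      st$varied_element[match(gene_ids, st$gene_id)]
  }
  truth_iso <- data.frame(
    gene_id = tx_gene, transcript_id = tx_ids,
    cp_cyto = unlist(cp_cyto, use.names = FALSE),
    cp_ribo = unlist(cp_ribo, use.names = FALSE),
    stringsAsFactors = FALSE)
  truth_iso$planted_cp_shift <- truth_iso$cp_ribo - truth_iso$cp_cyto

  ab <- abundance_table(counts, fpkm, lib_tab,
                        stats::setNames(tx_gene, tx_ids))
  list(abundance = ab,
       truth = list(genes = truth_genes, isoforms = truth_iso),
       lengths = lengths)
}

#' Generate catalog and counts in one call
#' @param params A [simulation_params()] object.
#' @return List with `catalog`, `abundance`, `truth`, `lengths`.
#' @export
simulate_experiment <- function(params) {
  catalog <- generate_catalog(params)
  sim <- simulate_counts(catalog, params)
  c(list(catalog = catalog), sim)
}
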