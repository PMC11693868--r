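#' Pipeline run configuration
#'
#' Bundles input locations (or a simulation), the four library
#' specifications, and every stage threshold with its default. Printed
#' thresholds of the underlying study design: |log2FC| >= 1, FPKM >= 1 in at
#' least one condition, adjusted p <= 0.001 for differential calling, and a
#' normalized-TE difference > 0.5 for differential TE.
#'
#' @param outdir Output directory.
#' @param gtf,quant,gmt Input paths (GTF catalog, merged quantification TSV,
#'   optional GMT gene sets). Ignored when `simulate` is given.
#' @param libraries data.frame of four [library_spec()] rows (required with
#'   `quant`).
#' @param simulate Optional [simulation_params()]; when given the pipeline
#'   generates its own inputs and evaluates calls against the truth.
#' @param min_abs_log2fc,min_fpkm,max_p_adj,fc_pseudocount Differential
#'   calling thresholds, see [call_differential()].
#' @param delta_te,te_norm Differential-TE threshold and normalization
#'   method, see [te_analysis()].
#' @param alpha,min_tx_fpkm,min_expected,chi_pseudocount Isoform-stage
#'   settings, see [isoform_selection_analysis()].
#' @param dominant_cp,dominant_ratio,cp_units Dominance rule and CP units,
#'   see [isoform_selection_analysis()].
#' @param seed Integer seed recorded in the run log.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(outdir, gtf = NULL, quant = NULL, gmt = NULL,
                       libraries = NULL, simulate = NULL,
                       min_abs_log2fc = 1, min_fpkm = 1, max_p_adj = 0.001,
                       fc_pseudocount = 0.25, delta_te = 0.5,
                       te_norm = "rank", alpha = 0.05, min_tx_fpkm = 1,
                       min_expected = 5, chi_pseudocount = 0.5,
                       dominant_cp = 0.5, dominant_ratio = 2,
                       cp_units = "count", seed = 1) {
  structure(list(outdir = outdir, gtf = gtf, quant = quant, gmt = gmt,
                 libraries = libraries, simulate = simulate,
                 min_abs_log2fc = min_abs_log2fc, min_fpkm = min_fpkm,
                 max_p_adj = max_p_adj, fc_pseudocount = fc_pseudocount,
                 delta_te = delta_te, te_norm = te_norm, alpha = alpha,
                 min_tx_fpkm = min_tx_fpkm, min_expected = min_expected,
                 chi_pseudocount = chi_pseudocount,
                 dominant_cp = dominant_cp, dominant_ratio = dominant_ratio,
                 cp_units = cp_units, seed = seed),
            class = "RunConfig")
}

#' Validate a run configuration
#'
#' @param config A [run_config()] object.
#' @return Character vector of violations; empty iff the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.character(config$outdir) && nzchar(config$outdir),
      "outdir: must be a non-empty path")
  chk(config$delta_te > 0 && config$delta_te <= 1,
      "delta_te: must be in (0,1]")
  chk(config$alpha > 0 && config$alpha <= 1, "alpha: must be in (0,1]")
  chk(config$max_p_adj > 0 && config$max_p_adj <= 1,
      "max_p_adj: must be in (0,1]")
  chk(config$min_abs_log2fc >= 0, "min_abs_log2fc: must be >= 0")
  chk(config$min_fpkm >= 0, "min_fpkm: must be >= 0")
  chk(config$min_tx_fpkm >= 0, "min_tx_fpkm: must be >= 0")
  chk(config$fc_pseudocount >= 0, "fc_pseudocount: must be >= 0")
  chk(config$chi_pseudocount >= 0, "chi_pseudocount: must be >= 0")
  chk(config$min_expected >= 0, "min_expected: must be >= 0")
  chk(config$dominant_cp > 0 && config$dominant_cp <= 1,
      "dominant_cp: must be in (0,1]")
  chk(config$dominant_ratio >= 1, "dominant_ratio: must be >= 1")
  chk(config$te_norm %in% c("rank", "minmax"),
      "te_norm: must be 'rank' or 'minmax'")
  chk(config$cp_units %in% c("count", "fpkm"),
      "cp_units: must be 'count' or 'fpkm'")
  if (is.null(config$simulate)) {
    chk(!is.null(config$gtf), "gtf: required unless simulating")
    chk(!is.null(config$quant), "quant: required unless simulating")
    if (is.null(config$libraries)) {
      v <- c(v, "libraries: required unless simulating")
    } else {
      for (cond in c("A", "B")) {
        for (fr in c("cytosolic", "ribosome")) {
          hit <- config$libraries$condition == cond &
            config$libraries$fraction == fr
          if (!any(hit)) {
            v <- c(v, sprintf("libraries: missing (%s, %s) library",
                              cond, fr))
          }
        }
      }
    }
  } else {
    chk(inherits(config$simulate, "SimulationParams"),
        "simulate: must be a simulation_params() object")
  }
  v
}

#' Run the full co-profiling pipeline
#'
#' Orchestrates data loading (or simulation), DEG/DTG calling, TE analysis,
#' the per-condition isoform-selection analysis, and optional gene-set
#' enrichment of the DEGs; writes every stage table, a `summary.tsv`, the
#' serialized config, and a `MANIFEST` with md5 checksums. On a stage
#' failure, partial outputs and a MANIFEST of completed stages are
#' retained.
#'
#' @param config A valid [run_config()].
#' @return Invisibly, a list with the summary data.frame and the stage
#'   results.
#' @export
run_full_pipeline <- function(config) {
  v <- validate_config(config)
  if (length(v) > 0) {
    stop("invalid config:\n  ", paste(v, collapse = "\n  "))
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  completed <- character(0)
  outputs <- character(0)
  finish_manifest <- function() {
    files <- file.path(outdir, outputs)
    sums <- tools::md5sum(files)
    lines <- sprintf("%s  %s", unname(sums), outputs)
    writeLines(c(sprintf("# completed stages: %s",
                         paste(completed, collapse = ", ")), lines),
               file.path(outdir, "MANIFEST"))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      finish_manifest()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    completed <<- c(completed, name)
    res
  }

  cfg_ser <- config
  cfg_ser$libraries <- if (is.null(config$libraries)) NULL else
    as.list(config$libraries)
  cfg_ser$simulate <- if (is.null(config$simulate)) NULL else
    unclass(config$simulate)
  yaml::write_yaml(lapply(unclass(cfg_ser), function(x)
    if (is.null(x)) "" else x), file.path(outdir, "config.yaml"))
  outputs <- c(outputs, "config.yaml")

  dat <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- simulate_experiment(config$simulate)
      export_gtf(sim$catalog, file.path(outdir, "catalog.gtf"))
      write_quantification(sim$abundance, sim$lengths,
                           file.path(outdir, "quantification.tsv"))
      write_results_table(sim$truth$genes, file.path(outdir,
                                                     "truth_genes.tsv"))
      outputs <<- c(outputs, "catalog.gtf", "quantification.tsv",
                    "truth_genes.tsv")
      sim
    } else {
      catalog <- parse_gtf(config$gtf)
      ab <- read_quantification(config$quant, config$libraries, catalog)
      list(catalog = catalog, abundance = ab, truth = NULL)
    }
  })
  ab <- dat$abundance
  catalog <- dat$catalog

  de <- stage("expression", {
    calls <- call_deg_dtg(ab, min_abs_log2fc = config$min_abs_log2fc,
                          min_fpkm = config$min_fpkm,
                          max_p_adj = config$max_p_adj,
                          pseudocount = config$fc_pseudocount)
    tab <- merge(calls$transcriptome, calls$translatome, by = "gene_id",
                 suffixes = c("_txome", "_tlome"))
    write_results_table(tab, file.path(outdir, "gene_calls.tsv"))
    outputs <<- c(outputs, "gene_calls.tsv")
    calls
  })

  te <- stage("te", {
    res <- te_analysis(ab, min_fpkm = config$min_fpkm,
                       method = config$te_norm,
                       delta_threshold = config$delta_te)
    write_results_table(res$calls, file.path(outdir, "te_calls.tsv"))
    outputs <<- c(outputs, "te_calls.tsv")
    res
  })

  iso <- stage("isoform", {
    per_cond <- lapply(c("A", "B"), function(cond) {
      isoform_selection_analysis(
        ab, cond, catalog = catalog, min_tx_fpkm = config$min_tx_fpkm,
        min_expected = config$min_expected,
        pseudocount = config$chi_pseudocount, alpha = config$alpha,
        dominant_cp = config$dominant_cp,
        dominant_ratio = config$dominant_ratio, units = config$cp_units)
    })
    names(per_cond) <- c("A", "B")
    gtab <- do.call(rbind, lapply(names(per_cond), function(cond) {
      cbind(condition = cond, per_cond[[cond]]$genes)
    }))
    itab <- do.call(rbind, lapply(names(per_cond), function(cond) {
      cbind(condition = cond, per_cond[[cond]]$isoforms)
    }))
    write_results_table(gtab, file.path(outdir, "isoform_selection.tsv"))
    write_results_table(itab, file.path(outdir, "isoform_diffcp.tsv"))
    outputs <<- c(outputs, "isoform_selection.tsv", "isoform_diffcp.tsv")
    per_cond
  })

  enr <- NULL
  if (!is.null(config$gmt)) {
    enr <- stage("enrich", {
      collection <- read_gmt(config$gmt)
      txome <- de$transcriptome
      universe <- txome$gene_id[txome$tested]
      query <- txome$gene_id[txome$flag != "ns"]
      res <- hypergeometric_enrichment(query, universe, collection,
                                       alpha = config$alpha)
      write_results_table(res, file.path(outdir, "enrichment.tsv"))
      outputs <<- c(outputs, "enrichment.tsv")
      res
    })
  }

  summary_tab <- stage("summary", {
    deg <- de$transcriptome
    dtg <- de$translatome
    ov <- overlap_calls(deg$gene_id[deg$flag != "ns"],
                        dtg$gene_id[dtg$flag != "ns"])
    sel_a <- iso$A$genes
    sel_b <- iso$B$genes
    sel_ov <- overlap_calls(sel_a$gene_id[sel_a$selected],
                            sel_b$gene_id[sel_b$selected])
    dom_fracs <- function(tab) {
      st <- tab$dominant_status[tab$n_expressed_union >= 1]
      c(unchanged = mean(st == "unchanged"),
        switched = mean(st == "switched"),
        undefined = mean(st == "undefined"))
    }
    struct_fracs <- function(tab) {
      s <- tab$structural_diff[tab$selected & !is.na(tab$structural_diff)]
      if (length(s) == 0) return(c(utr = NA_real_, cds = NA_real_))
      c(utr = mean(grepl("utr", s)), cds = mean(grepl("cds", s)))
    }
    mi <- lapply(c("A", "B"), function(cond) {
      lapply(c("cytosolic", "ribosome"), function(fr) {
        multi_isoform_stats(ab, cond, fr, config$min_tx_fpkm)
      })
    })
    row <- function(section, metric, value) {
      data.frame(section = section, metric = metric,
                 value = as.numeric(value), stringsAsFactors = FALSE)
    }
    tab <- rbind(
      row("deg", "n_tested", sum(deg$tested)),
      row("deg", "n_deg", sum(deg$flag != "ns")),
      row("deg", "n_up_A", sum(deg$flag == "up_A")),
      row("deg", "n_up_B", sum(deg$flag == "up_B")),
      row("dtg", "n_tested", sum(dtg$tested)),
      row("dtg", "n_dtg", sum(dtg$flag != "ns")),
      row("dtg", "n_up_A", sum(dtg$flag == "up_A")),
      row("dtg", "n_up_B", sum(dtg$flag == "up_B")),
      row("overlap", "n_shared", ov$n_shared),
      row("overlap", "frac_of_deg", ov$frac_of_deg),
      row("te", "n_eligible_A", te$n_eligible_a),
      row("te", "n_eligible_B", te$n_eligible_b),
      row("te", "n_common", te$n_common),
      row("te", "n_diff_te", sum(te$calls$flag != "ns")),
      row("te", "n_te_up_A", sum(te$calls$flag == "up_A")),
      row("te", "n_te_up_B", sum(te$calls$flag == "up_B")),
      row("isoform_A", "n_testable", sum(sel_a$testable)),
      row("isoform_A", "n_selected", sum(sel_a$selected)),
      row("isoform_B", "n_testable", sum(sel_b$testable)),
      row("isoform_B", "n_selected", sum(sel_b$selected)),
      row("isoform", "n_selected_shared", sel_ov$n_shared),
      row("dominant_A", "frac_unchanged", dom_fracs(sel_a)["unchanged"]),
      row("dominant_A", "frac_switched", dom_fracs(sel_a)["switched"]),
      row("dominant_A", "frac_undefined", dom_fracs(sel_a)["undefined"]),
      row("dominant_B", "frac_unchanged", dom_fracs(sel_b)["unchanged"]),
      row("dominant_B", "frac_switched", dom_fracs(sel_b)["switched"]),
      row("dominant_B", "frac_undefined", dom_fracs(sel_b)["undefined"]),
      row("structural_A", "frac_utr", struct_fracs(sel_a)["utr"]),
      row("structural_A", "frac_cds", struct_fracs(sel_a)["cds"]),
      row("structural_B", "frac_utr", struct_fracs(sel_b)["utr"]),
      row("structural_B", "frac_cds", struct_fracs(sel_b)["cds"]),
      row("multi_isoform_A", "prop_cytosolic", mi[[1]][[1]]$proportion),
      row("multi_isoform_A", "prop_ribosome", mi[[1]][[2]]$proportion),
      row("multi_isoform_A", "prop_test_p",
          proportion_test(mi[[1]][[2]]$n_genes_ge2_expressed,
                          mi[[1]][[2]]$n_genes_total,
                          mi[[1]][[1]]$n_genes_ge2_expressed,
                          mi[[1]][[1]]$n_genes_total)),
      row("multi_isoform_B", "prop_cytosolic", mi[[2]][[1]]$proportion),
      row("multi_isoform_B", "prop_ribosome", mi[[2]][[2]]$proportion),
      row("multi_isoform_B", "prop_test_p",
          proportion_test(mi[[2]][[2]]$n_genes_ge2_expressed,
                          mi[[2]][[2]]$n_genes_total,
                          mi[[2]][[1]]$n_genes_ge2_expressed,
                          mi[[2]][[1]]$n_genes_total)),
      row("run", "seed", config$seed))
    write_results_table(tab, file.path(outdir, "summary.tsv"))
    outputs <<- c(outputs, "summary.tsv")
    tab
  })

  finish_manifest()
  invisible(list(summary = summary_tab, expression = de, te = te,
                 isoform = iso, enrichment = enr, data = dat))
}
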