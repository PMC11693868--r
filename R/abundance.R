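#' Library specification
#'
#' Describes one sequencing library of the four-library design:
#' two conditions (`"A"`, `"B"`; e.g. embryo vs cultured cells) crossed with
#' two fractions (`"cytosolic"`, `"ribosome"`).
#'
#' @param library_id Unique library identifier (used as column name).
#' @param condition `"A"` or `"B"`.
#' @param fraction `"cytosolic"` or `"ribosome"`.
#' @param total_mapped_reads Positive number of mapped reads (FPKM
#'   denominator and Fisher-test margin).
#' @return A one-row data.frame.
#' @export
library_spec <- function(library_id, condition, fraction, total_mapped_reads) {
  condition <- match.arg(condition, c("A", "B"))
  fraction <- match.arg(fraction, c("cytosolic", "ribosome"))
  if (!is.numeric(total_mapped_reads) || total_mapped_reads < 1) {
    stop("total_mapped_reads must be >= 1")
  }
  data.frame(library_id = library_id, condition = condition,
             fraction = fraction, total_mapped_reads = total_mapped_reads,
             stringsAsFactors = FALSE)
}

#' Transcript-by-library abundance table
#'
#' Container pairing an estimated-count matrix and an FPKM matrix over the
#' same transcripts and libraries, with library metadata and the
#' transcript-to-gene map used for gene-level aggregation.
#'
#' @param counts,fpkm Numeric matrices, rows = transcripts, columns =
#'   libraries; identical dimnames.
#' @param libraries data.frame of [library_spec()] rows, one per column.
#' @param tx2gene Named character vector: transcript_id -> gene_id, covering
#'   every row.
#' @return An object of class `AbundanceTable`.
#' @export
abundance_table <- function(counts, fpkm, libraries, tx2gene) {
  stopifnot(is.matrix(counts), is.matrix(fpkm))
  if (!identical(dim(counts), dim(fpkm)) ||
      !identical(dimnames(counts), dimnames(fpkm))) {
    stop("counts and fpkm must share shape and dimnames")
  }
  if (any(counts < 0) || any(fpkm < 0)) stop("negative abundance value")
  if (anyDuplicated(rownames(counts))) stop("duplicate transcript_id")
  if (!setequal(colnames(counts), libraries$library_id) ||
      anyDuplicated(libraries$library_id)) {
    stop("library metadata does not match matrix columns")
  }
  key <- paste(libraries$condition, libraries$fraction)
  reps <- ave(seq_along(key), key, FUN = length)
  missing_tx <- setdiff(rownames(counts), names(tx2gene))
  if (length(missing_tx) > 0) {
    stop("transcripts missing from tx2gene map: ",
         paste(utils::head(missing_tx, 3), collapse = ", "))
  }
  libraries <- libraries[match(colnames(counts), libraries$library_id), ,
                         drop = FALSE]
  rownames(libraries) <- libraries$library_id
  structure(list(counts = counts, fpkm = fpkm, libraries = libraries,
                 tx2gene = tx2gene[rownames(counts)]),
            class = "AbundanceTable")
}

#' @export
print.AbundanceTable <- function(x, ...) {
  cat(sprintf("AbundanceTable: %d transcripts (%d genes) x %d libraries\n",
              nrow(x$counts), length(unique(x$tx2gene)), ncol(x$counts)))
  print(x$libraries, row.names = FALSE)
  invisible(x)
}

#' Find the library id for a condition/fraction pair
#' @param ab An `AbundanceTable`.
#' @param condition `"A"` or `"B"`.
#' @param fraction `"cytosolic"` or `"ribosome"`.
#' @return The matching library_id (first match if replicated).
#' @export
library_id <- function(ab, condition, fraction) {
  lib <- ab$libraries
  hit <- lib$library_id[lib$condition == condition & lib$fraction == fraction]
  if (length(hit) == 0) {
    stop(sprintf("no library for condition %s, fraction %s",
                 condition, fraction))
  }
  hit[1]
}

#' Gene-level aggregation
#'
#' Gene count (or FPKM) is the exact sum of the gene's transcripts.
#'
#' @param ab An `AbundanceTable`.
#' @return Gene-by-library numeric matrix.
#' @export
gene_counts <- function(ab) rowsum(ab$counts, group = ab$tx2gene)

#' @rdname gene_counts
#' @export
gene_fpkm <- function(ab) rowsum(ab$fpkm, group = ab$tx2gene)

#' Read a merged quantification table
#'
#' Expects a TSV with header `transcript_id`, `gene_id`, `length`, then for
#' every library `<library_id>_count` and `<library_id>_fpkm` columns.
#' Transcripts present in `catalog` but absent from the table are filled
#' with zeros (assemblers drop unexpressed isoforms).
#'
#' @param path TSV path.
#' @param specs data.frame of [library_spec()] rows.
#' @param catalog Optional `TranscriptCatalog` used to complete missing
#'   transcripts with zero rows.
#' @return An [abundance_table()].
#' @export
read_quantification <- function(path, specs, catalog = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("transcript_id", "gene_id", "length")) {
    if (!col %in% names(df)) stop("quantification table lacks column ", col)
  }
  if (anyDuplicated(df$transcript_id)) {
    stop("duplicate transcript_id in quantification table: ",
         df$transcript_id[duplicated(df$transcript_id)][1])
  }
  for (lib in specs$library_id) {
    for (suff in c("_count", "_fpkm")) {
      col <- paste0(lib, suff)
      if (!col %in% names(df)) {
        stop("missing column for library ", lib, ": ", col)
      }
      if (any(is.na(df[[col]]))) df[[col]][is.na(df[[col]])] <- 0
      if (any(df[[col]] < 0)) {
        stop("negative value in column ", col)
      }
    }
  }
  counts <- as.matrix(df[, paste0(specs$library_id, "_count"), drop = FALSE])
  fpkm <- as.matrix(df[, paste0(specs$library_id, "_fpkm"), drop = FALSE])
  dimnames(counts) <- dimnames(fpkm) <- list(df$transcript_id,
                                             specs$library_id)
  tx2gene <- stats::setNames(df$gene_id, df$transcript_id)
  if (!is.null(catalog)) {
    extra <- setdiff(catalog$transcripts$transcript_id, df$transcript_id)
    if (length(extra) > 0) {
      zero <- matrix(0, nrow = length(extra), ncol = ncol(counts),
                     dimnames = list(extra, colnames(counts)))
      counts <- rbind(counts, zero)
      fpkm <- rbind(fpkm, zero)
      tx2gene <- c(tx2gene,
                   stats::setNames(
                     catalog$transcripts[extra, "gene_id"], extra))
    }
  }
  abundance_table(counts, fpkm, specs, tx2gene)
}

#' Write a result table as deterministic TSV
#'
#' Rows are sorted by `gene_id` then `transcript_id` (when present), floats
#' are rendered at 6 significant digits, so repeated writes of the same table
#' are byte-identical.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_results_table <- function(table, path) {
  if (is.null(table)) stop("table must be non-null")
  table <- as.data.frame(table)
  ord_cols <- intersect(c("gene_id", "transcript_id"), names(table))
  if (length(ord_cols) > 0) {
    table <- table[do.call(order, table[ord_cols]), , drop = FALSE]
  }
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) "NA" else sprintf("%.6g", v)
      }, character(1))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read back a TSV written by [write_results_table()]
#' @param path TSV path.
#' @return data.frame with types re-inferred.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an abundance table as a merged quantification TSV
#'
#' Inverse of [read_quantification()]; full precision is kept via
#' `%.10g` so round-trips preserve simulated counts.
#'
#' @param ab An `AbundanceTable`.
#' @param lengths Named per-transcript length vector (nt).
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_quantification <- function(ab, lengths, path) {
  tx <- rownames(ab$counts)
  df <- data.frame(transcript_id = tx, gene_id = unname(ab$tx2gene[tx]),
                   length = unname(lengths[tx]), stringsAsFactors = FALSE)
  for (lib in colnames(ab$counts)) {
    df[[paste0(lib, "_count")]] <- sprintf("%.10g", ab$counts[, lib])
    df[[paste0(lib, "_fpkm")]] <- sprintf("%.10g", ab$fpkm[, lib])
  }
  df <- df[order(df$gene_id, df$transcript_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
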