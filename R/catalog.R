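#' Transcript catalog
#'
#' A `TranscriptCatalog` holds gene -> transcript -> feature models derived
#' from a GTF (or built by [generate_catalog()]). All coordinates are stored
#' 0-based half-open; GTF input/output converts from/to the 1-based inclusive
#' convention of the format.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`.
#' @param features data.frame with columns `transcript_id`, `type` (one of
#'   `"exon"`, `"cds"`, `"utr5"`, `"utr3"`), `start`, `end` (0-based
#'   half-open).
#' @return An object of class `TranscriptCatalog` with elements
#'   `transcripts` (per-transcript table including exonic `length`) and
#'   `features` (interval table).
#' @export
transcript_catalog <- function(transcripts, features) {
  stopifnot(is.data.frame(transcripts), is.data.frame(features))
  needed <- c("transcript_id", "gene_id", "chrom", "strand")
  if (!all(needed %in% names(transcripts))) {
    stop("transcripts table must have columns: ",
         paste(needed, collapse = ", "))
  }
  if (nrow(features) > 0 &&
      !all(c("transcript_id", "type", "start", "end") %in% names(features))) {
    stop("features table must have columns: transcript_id, type, start, end")
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicate transcript_id in catalog")
  }
  transcripts <- transcripts[order(transcripts$gene_id,
                                   transcripts$transcript_id), , drop = FALSE]
  rownames(transcripts) <- transcripts$transcript_id
  if (nrow(features) > 0) {
    features <- features[order(features$transcript_id, features$type,
                               features$start), , drop = FALSE]
    rownames(features) <- NULL
    unknown <- setdiff(features$transcript_id, transcripts$transcript_id)
    if (length(unknown) > 0) {
      stop("features reference unknown transcripts: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
  }
  ex <- features[features$type == "exon", , drop = FALSE]
  len <- rep(0, nrow(transcripts))
  names(len) <- transcripts$transcript_id
  if (nrow(ex) > 0) {
    w <- tapply(ex$end - ex$start, ex$transcript_id, sum)
    len[names(w)] <- as.numeric(w)
  }
  transcripts$length <- as.numeric(len)
  obj <- structure(list(transcripts = transcripts, features = features),
                   class = "TranscriptCatalog")
  validate_catalog(obj)
  obj
}

#' @export
print.TranscriptCatalog <- function(x, ...) {
  cat(sprintf("TranscriptCatalog: %d genes, %d transcripts (%d coding)\n",
              length(unique(x$transcripts$gene_id)),
              nrow(x$transcripts),
              length(unique(
                x$features$transcript_id[x$features$type == "cds"]))))
  invisible(x)
}

#' Number of genes / transcripts in a catalog
#' @param catalog A `TranscriptCatalog`.
#' @return Integer count.
#' @export
n_genes <- function(catalog) length(unique(catalog$transcripts$gene_id))

#' @rdname n_genes
#' @export
n_transcripts <- function(catalog) nrow(catalog$transcripts)

#' Gene to transcript mapping
#' @param catalog A `TranscriptCatalog`.
#' @return Named list: gene_id -> character vector of transcript ids.
#' @export
gene_transcripts <- function(catalog) {
  split(catalog$transcripts$transcript_id, catalog$transcripts$gene_id)
}

#' Feature intervals of one transcript
#'
#' @param catalog A `TranscriptCatalog`.
#' @param transcript_id Transcript identifier.
#' @param type One of `"exon"`, `"cds"`, `"utr5"`, `"utr3"`.
#' @return Two-column matrix (`start`, `end`), 0-based half-open, sorted;
#'   zero rows when the transcript has no such feature.
#' @export
feature_intervals <- function(catalog, transcript_id, type) {
  if (!transcript_id %in% catalog$transcripts$transcript_id) {
    stop("unknown transcript: ", transcript_id)
  }
  f <- catalog$features
  f <- f[f$transcript_id == transcript_id & f$type == type, , drop = FALSE]
  m <- cbind(start = f$start, end = f$end)
  m[order(m[, 1]), , drop = FALSE]
}

## Merge overlapping/adjacent intervals into a canonical sorted form so that
## interval SETS can be compared with identical().
normalize_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0) {
    return(cbind(start = numeric(0), end = numeric(0)))
  }
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      j <- nrow(out)
      if (m[i, 1] <= out[j, 2]) {
        out[j, 2] <- max(out[j, 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

interval_setdiff <- function(a, b) {
  ra <- IRanges::IRanges(start = a[, 1] + 1, end = a[, 2])
  rb <- IRanges::IRanges(start = b[, 1] + 1, end = b[, 2])
  d <- IRanges::setdiff(ra, rb)
  cbind(start = IRanges::start(d) - 1, end = IRanges::end(d))
}

## Split the exonic-minus-CDS remainder into 5'/3' UTR by position relative
## to the CDS genomic span, honouring strand.
derive_utrs <- function(exons, cds, strand) {
  if (nrow(cds) == 0) {
    empty <- cbind(start = numeric(0), end = numeric(0))
    return(list(utr5 = empty, utr3 = empty))
  }
  rest <- interval_setdiff(normalize_intervals(exons), normalize_intervals(cds))
  left <- rest[rest[, 2] <= min(cds[, 1]), , drop = FALSE]
  right <- rest[rest[, 1] >= max(cds[, 2]), , drop = FALSE]
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

#' Validate catalog invariants
#'
#' Checks that every transcript belongs to exactly one gene, exons are sorted
#' and non-overlapping, the CDS is contained in the exons, and (for coding
#' transcripts) UTR + CDS lengths add up to the exonic length.
#'
#' @param catalog A `TranscriptCatalog`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_catalog <- function(catalog) {
  tx <- catalog$transcripts
  f <- catalog$features
  if (nrow(tx) == 0) return(invisible(TRUE))
  ex <- f[f$type == "exon", , drop = FALSE]
  no_ex <- setdiff(tx$transcript_id, unique(ex$transcript_id))
  if (length(no_ex) > 0) stop("transcript with no exons: ", no_ex[1])
  if (any(ex$end <= ex$start)) {
    stop("empty exon interval in ",
         ex$transcript_id[which(ex$end <= ex$start)[1]])
  }
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  if (nrow(ex) > 1) {
    same <- ex$transcript_id[-1] == ex$transcript_id[-nrow(ex)]
    bad <- same & ex$start[-1] < ex$end[-nrow(ex)]
    if (any(bad)) {
      stop("overlapping exons in transcript ", ex$transcript_id[-1][bad][1])
    }
  }
  cds <- f[f$type == "cds", , drop = FALSE]
  if (nrow(cds) > 0) {
    lev <- unique(tx$transcript_id)
    gr_ex <- GenomicRanges::GRanges(
      factor(ex$transcript_id, levels = lev),
      IRanges::IRanges(ex$start + 1, ex$end))
    gr_cds <- GenomicRanges::GRanges(
      factor(cds$transcript_id, levels = lev),
      IRanges::IRanges(cds$start + 1, cds$end))
    within <- GenomicRanges::countOverlaps(gr_cds, gr_ex, type = "within")
    if (any(within == 0)) {
      stop("CDS extends outside exons in transcript ",
           cds$transcript_id[which(within == 0)[1]])
    }
    cds_len <- tapply(cds$end - cds$start, cds$transcript_id, sum)
    utr <- f[f$type %in% c("utr5", "utr3"), , drop = FALSE]
    utr_len <- if (nrow(utr) > 0) {
      tapply(utr$end - utr$start, utr$transcript_id, sum)
    } else numeric(0)
    ex_len <- tapply(ex$end - ex$start, ex$transcript_id, sum)
    coding <- names(cds_len)
    u <- utr_len[coding]
    u[is.na(u)] <- 0
    bad <- abs(as.numeric(cds_len) + as.numeric(u) -
                 as.numeric(ex_len[coding])) > 1e-9
    if (any(bad)) {
      stop("utr5 + cds + utr3 lengths do not cover exons in ",
           coding[bad][1])
    }
  }
  invisible(TRUE)
}

#' Parse a GTF file into a transcript catalog
#'
#' Reads an Ensembl-style GTF (1-based inclusive coordinates with `gene_id`
#' and `transcript_id` attributes), keeps `exon` and `CDS` rows, and derives
#' 5'/3' UTR intervals as the strand-oriented exon-minus-CDS set difference.
#' Transcripts without CDS rows get empty UTRs and are flagged via
#' `length(feature_intervals(., tx, "cds")) == 0`.
#'
#' @param path Path to a GTF file.
#' @return A [transcript_catalog()].
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  if (!any(body)) {
    return(transcript_catalog(
      data.frame(transcript_id = character(0), gene_id = character(0),
                 chrom = character(0), strand = character(0)),
      data.frame(transcript_id = character(0), type = character(0),
                 start = numeric(0), end = numeric(0))))
  }
  for (i in which(body)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9 ||
        is.na(suppressWarnings(as.numeric(fields[4]))) ||
        is.na(suppressWarnings(as.numeric(fields[5])))) {
      stop(sprintf("malformed GTF line %d in %s", i, path))
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  keep <- tolower(as.character(meta$type)) %in% c("exon", "cds")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  if (length(gr) == 0) stop("GTF contains no exon or CDS rows: ", path)
  if (any(is.na(meta$transcript_id)) || any(is.na(meta$gene_id))) {
    stop("exon/CDS row missing gene_id or transcript_id attribute")
  }
  df <- data.frame(
    transcript_id = as.character(meta$transcript_id),
    gene_id = as.character(meta$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = tolower(as.character(meta$type)),
    start = GenomicRanges::start(gr) - 1,   # to 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE)
  gene_per_tx <- tapply(df$gene_id, df$transcript_id,
                        function(g) length(unique(g)))
  if (any(gene_per_tx > 1)) {
    stop("transcript assigned to multiple genes: ",
         paste(names(gene_per_tx)[gene_per_tx > 1], collapse = ", "))
  }
  tx_tab <- unique(df[, c("transcript_id", "gene_id", "chrom", "strand")])
  feats <- list()
  for (k in seq_len(nrow(tx_tab))) {
    id <- tx_tab$transcript_id[k]
    sub <- df[df$transcript_id == id, , drop = FALSE]
    ex <- sub[sub$type == "exon", c("start", "end"), drop = FALSE]
    cds <- sub[sub$type == "cds", c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0) stop("transcript with no exons: ", id)
    exm <- as.matrix(ex)
    cdm <- as.matrix(cds)
    utrs <- derive_utrs(exm, cdm, tx_tab$strand[k])
    blocks <- rbind(
      data.frame(type = "exon", start = exm[, 1], end = exm[, 2]),
      if (nrow(cdm) > 0)
        data.frame(type = "cds", start = cdm[, 1], end = cdm[, 2]),
      if (nrow(utrs$utr5) > 0)
        data.frame(type = "utr5", start = utrs$utr5[, 1], end = utrs$utr5[, 2]),
      if (nrow(utrs$utr3) > 0)
        data.frame(type = "utr3", start = utrs$utr3[, 1], end = utrs$utr3[, 2]))
    blocks$transcript_id <- id
    feats[[k]] <- blocks
  }
  features <- do.call(rbind, feats)[, c("transcript_id", "type",
                                        "start", "end")]
  transcript_catalog(tx_tab, features)
}

#' Export a catalog to GTF
#'
#' Writes exon and CDS rows (UTRs are derivable and not emitted, matching
#' assembler output). Coordinates are converted back to 1-based inclusive.
#'
#' @param catalog A `TranscriptCatalog`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
export_gtf <- function(catalog, path) {
  f <- catalog$features
  f <- f[f$type %in% c("exon", "cds"), , drop = FALSE]
  tx <- catalog$transcripts
  idx <- match(f$transcript_id, tx$transcript_id)
  ord <- order(tx$gene_id[idx], f$transcript_id, f$type, f$start)
  f <- f[ord, , drop = FALSE]
  idx <- idx[ord]
  gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom[idx],
    ranges = IRanges::IRanges(start = f$start + 1, end = f$end),
    strand = tx$strand[idx])
  S4Vectors::mcols(gr)$type <- ifelse(f$type == "cds", "CDS", "exon")
  S4Vectors::mcols(gr)$source <- "ribosel"
  S4Vectors::mcols(gr)$gene_id <- tx$gene_id[idx]
  S4Vectors::mcols(gr)$transcript_id <- f$transcript_id
  # phase is unknown for assembled models and unused downstream
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  invisible(path)
}
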