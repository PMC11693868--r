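#' Read a GMT gene-set file
#'
#' Each line: term id, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of gene-id character vectors with a `description`
#'   attribute per element; class `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: need term, description, genes", i))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop(sprintf("empty gene set at GMT line %d", i))
    s <- genes
    attr(s, "description") <- fields[2]
    sets[[fields[1]]] <- s
  }
  structure(sets, class = "GeneSetCollection")
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests over-representation of the query in the term with
#' the upper hypergeometric tail `P(X >= k)`, where `N = |universe|`,
#' `K = |term intersect universe|`, `n = |query|`, `k = |term intersect
#' query|`. Terms are intersected with the universe before testing; BH
#' q-values are computed across the tested terms; output is sorted by q,
#' then p, then term id.
#'
#' @param query Character vector of genes (subset of `universe`).
#' @param universe Character vector, the background gene set.
#' @param collection A [read_gmt()] collection (or named list of gene sets).
#' @param alpha Significance threshold stored in the `significant` column.
#' @return data.frame with `term_id`, `description`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p_raw`, `q_value`, `significant`.
#' @export
hypergeometric_enrichment <- function(query, universe, collection,
                                      alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query must be a subset of the universe")
  }
  if (length(query) == 0) {
    warning("empty query: no terms tested")
    return(data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), fold_enrichment = numeric(0),
                      p_raw = numeric(0), q_value = numeric(0),
                      significant = logical(0)))
  }
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(collection[[term]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    desc <- attr(collection[[term]], "description")
    data.frame(term_id = term,
               description = if (is.null(desc)) "" else desc,
               k = k, K = K, n = n, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_raw = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0) {
    warning("no terms overlap the universe")
    return(data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), fold_enrichment = numeric(0),
                      p_raw = numeric(0), q_value = numeric(0),
                      significant = logical(0)))
  }
  res$q_value <- stats::p.adjust(res$p_raw, method = "BH")
  res$significant <- res$q_value <= alpha
  res[order(res$q_value, res$p_raw, res$term_id), , drop = FALSE]
}

#' Head of a sorted enrichment table
#'
#' @param result Output of [hypergeometric_enrichment()] (already sorted).
#' @param n Number of top terms (default 10).
#' @return The first `min(n, nrow)` rows.
#' @export
top_terms <- function(result, n = 10) {
  if (n <= 0) stop("n must be positive")
  utils::head(result, n)
}
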