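# Fixtures and independent oracles shared across the suite.

# Write a small GTF from a list of rows: list(chrom, type, start1, end1,
# strand, gene, tx) using 1-based inclusive coordinates as in the format.
write_fixture_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- vapply(rows, function(r) {
    sprintf("%s\tfix\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], r[[6]], r[[7]])
  }, character(1))
  writeLines(lines, path)
  path
}

# Four-library AbundanceTable from a transcript-by-4 count matrix.
make_fixture_abundance <- function(counts, tx2gene, lengths = NULL,
                                   depth = 1e6) {
  colnames(counts) <- c("A_cyto", "A_ribo", "B_cyto", "B_ribo")
  specs <- rbind(library_spec("A_cyto", "A", "cytosolic", depth),
                 library_spec("A_ribo", "A", "ribosome", depth),
                 library_spec("B_cyto", "B", "cytosolic", depth),
                 library_spec("B_ribo", "B", "ribosome", depth))
  if (is.null(lengths)) {
    lengths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  }
  fpkm <- compute_fpkm(counts, lengths,
                       stats::setNames(rep(depth, 4), colnames(counts)))
  abundance_table(counts, fpkm, specs, tx2gene)
}

# Brute-force Pearson chi-square on an r x c table: explicit loop over
# cells, independent of the package implementation.
pearson_chi2_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); tot <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / tot
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  list(stat = stat, df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# Two-sided Fisher p by direct hypergeometric tail enumeration using
# log-binomial coefficients (no dhyper, no fisher.test).
fisher_enum_oracle <- function(x1, t1, x2, t2) {
  k <- x1 + x2
  supp <- max(0, k - t2):min(k, t1)
  logp <- lchoose(t1, supp) + lchoose(t2, k - supp) - lchoose(t1 + t2, k)
  p <- exp(logp)
  obs <- p[supp == x1]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Upper hypergeometric tail P(X >= k) by explicit combinatorial sum.
hyper_tail_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
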