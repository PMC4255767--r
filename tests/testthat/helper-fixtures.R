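# Shared fixture builders. Everything is generated in code; no data files.

# hap_matrix from a bare 0/1 matrix, sites at 1000, 2000, ...
toy_hm <- function(m, polarized = TRUE, chrom = "chr1", pos = NULL) {
  m <- as.matrix(m)
  if (is.null(pos)) pos <- seq_len(ncol(m)) * 1000L
  hap_matrix(m, data.frame(chrom = chrom, pos = pos,
                           id = paste0("v", seq_len(ncol(m))),
                           ref = "A", alt = "G", aa = "A",
                           stringsAsFactors = FALSE),
             hap_ids = as.vector(rbind(paste0("s", seq_len(nrow(m) / 2), "_1"),
                                       paste0("s", seq_len(nrow(m) / 2), "_2"))),
             polarized = polarized)
}

# independent O(n^2 S) oracle: mean pairwise difference count
pairwise_pi_oracle <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / (n * (n - 1) / 2)
}

# independent brute-force Tajima (1989) implementation used as the oracle
tajima_oracle <- function(m) {
  n <- nrow(m)
  cs <- colSums(m)
  S <- sum(cs > 0 & cs < n)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pairwise_pi_oracle(m) - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# write a small handcrafted phased VCF; returns its path
write_toy_vcf <- function(lines_body, samples = c("NA1", "NA2", "NA3"),
                          info_aa = TRUE) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           if (info_aa) '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "##contig=<ID=chr1>",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines_body), path)
  path
}

toy_panel <- function(samples = c("NA1", "NA2", "NA3"),
                      pops = c("YRI", "YRI", "CEU")) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation", paste(samples, pops, sep = "\t")), path)
  path
}

# random polymorphic 0/1 matrix with at least one segregating column
random_hm <- function(n, s, p = 0.3) {
  repeat {
    m <- matrix(rbinom(n * s, 1, p), n, s)
    cs <- colSums(m)
    if (any(cs > 0 & cs < n)) return(m)
  }
}
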