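#' Weir-Cockerham F_ST for two populations of haplotypes
#'
#' Variance-components estimator of Weir & Cockerham (1984) in its
#' haploid form (allele counts on phased haplotypes; no heterozygosity
#' term), for r = 2 populations. With `nb = (n1+n2)/2`,
#' `nc = 2 nb - (n1^2+n2^2)/(2 nb)`, weighted mean frequency `pb` and
#' among-population variance `s2 = sum n_i (p_i - pb)^2 / nb`:
#' `T1 = s2 - (pb(1-pb) - s2/2)/(nb-1)` and
#' `T2 = ((nc-1)/(nb-1)) pb(1-pb) + (1 + (nb-nc)/(nb-1)) s2/2`;
#' the estimate is `T1/T2`. Negative estimates are legitimate sampling
#' outcomes and are retained. A site monomorphic in both populations for
#' the same allele is undefined (NA).
#'
#' @param n1,n2 haplotype counts (>= 2) per population; vectorized.
#' @param p1,p2 allele frequencies (same allele in both populations).
#' @return Numeric vector of F_ST estimates.
#' @examples
#' wc_fst(10, 1, 10, 0)      # fixed difference: 1
#' wc_fst(10, 0.5, 10, 0.5)  # identical frequencies: -1/9
#' @export
wc_fst <- function(n1, p1, n2, p2) {
  if (any(n1 < 2 | n2 < 2)) stopf("need >= 2 haplotypes per population")
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1)) stopf("frequencies must lie in [0, 1]")
  nb <- (n1 + n2) / 2
  nc <- 2 * nb - (n1^2 + n2^2) / (2 * nb)
  pb <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pb)^2 + n2 * (p2 - pb)^2) / nb
  t1 <- s2 - (pb * (1 - pb) - s2 / 2) / (nb - 1)
  t2 <- ((nc - 1) / (nb - 1)) * pb * (1 - pb) + (1 + (nb - nc) / (nb - 1)) * s2 / 2
  out <- t1 / t2
  out[t2 == 0] <- NA_real_
  out
}

#' Minor-allele-frequency bin (50 classes)
#'
#' Maps a MAF in `[0, 0.5]` to one of 50 equal-width classes of width
#' 0.01; `maf = 0.5` falls in bin 49.
#'
#' @param maf minor allele frequency, vectorized; values above 0.5 are an
#'   error (fold first).
#' @return Integer bin index in `0..49`.
#' @export
maf_bin <- function(maf) {
  if (any(maf < 0 | maf > 0.5)) stopf("MAF must lie in [0, 0.5]; fold before binning")
  # epsilon guards against 23/100 landing at 23.000000000000004
  pmin(as.integer(floor(maf * 100 + 1e-9)), 49L)
}

#' Per-SNP F_ST scan for one population pair
#'
#' Computes the Weir-Cockerham estimate at every site polymorphic in the
#' pooled pair, together with the pooled MAF, its bin, and (when a
#' control null is supplied) the empirical percentile rank of the
#' estimate within its MAF class. Sites with undefined F_ST are excluded;
#' sites falling in control bins holding fewer than the null's
#' `min_bin_count` values get rank NA.
#'
#' @param x `hap_matrix` containing both populations' haplotypes
#'   (polarization irrelevant: F_ST uses only frequencies).
#' @param panel panel data.frame mapping samples to populations.
#' @param pop1,pop2 the two population labels (order fixes the reported
#'   comparison string `"pop1/pop2"`).
#' @param null optional `empirical_null` built by [build_null()] from
#'   control-region F_ST records with the same binning.
#' @return data.frame with columns `id, chrom, pos, comparison, n1, n2,
#'   p1, p2, maf, maf_bin, fst, rank`.
#' @export
fst_scan <- function(x, panel, pop1, pop2, null = NULL) {
  m1 <- hap_population(x, panel, pop1)
  m2 <- hap_population(x, panel, pop2)
  n1 <- n_haps(m1); n2 <- n_haps(m2)
  c1 <- colSums(m1$data); c2 <- colSums(m2$data)
  tot <- c1 + c2
  poly <- tot > 0 & tot < (n1 + n2)
  if (!any(poly))
    return(data.frame(id = character(0), chrom = character(0), pos = integer(0),
                      comparison = character(0), n1 = integer(0), n2 = integer(0),
                      p1 = numeric(0), p2 = numeric(0), maf = numeric(0),
                      maf_bin = integer(0), fst = numeric(0), rank = numeric(0)))
  p1 <- c1[poly] / n1; p2 <- c2[poly] / n2
  pbar <- tot[poly] / (n1 + n2)
  maf <- pmin(pbar, 1 - pbar)
  fst <- wc_fst(n1, p1, n2, p2)
  keep <- !is.na(fst)
  s <- x$sites[poly, , drop = FALSE][keep, , drop = FALSE]
  rec <- data.frame(id = s$id, chrom = s$chrom, pos = s$pos,
                    comparison = paste0(pop1, "/", pop2),
                    n1 = n1, n2 = n2, p1 = p1[keep], p2 = p2[keep],
                    maf = maf[keep], maf_bin = maf_bin(maf[keep]),
                    fst = fst[keep], rank = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(null))
    rec$rank <- null_rank(null, rec$fst, rec$maf_bin)
  rec
}
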