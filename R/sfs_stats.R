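# Site-frequency-spectrum estimators. All operate either on a hap_matrix
# or on a bare 0/1 matrix (haplotypes x sites); polarization is enforced
# only where the unfolded spectrum matters (theta_L, H, DH).

as_hap_data <- function(x, need_polarized = FALSE) {
  if (inherits(x, "hap_matrix")) {
    if (need_polarized && !x$polarized)
      stopf("this statistic requires a polarized hap_matrix (1 = derived)")
    x$data
  } else as.matrix(x)  # bare matrices are taken as already 1 = derived
}

# derived-allele counts of polymorphic columns
seg_counts <- function(d) {
  if (ncol(d) == 0) return(integer(0))
  cs <- colSums(d)
  cs[cs > 0 & cs < nrow(d)]
}

#' Unfolded site frequency spectrum
#'
#' Counts, for each derived-allele copy number `i = 1..n-1`, the number of
#' polymorphic sites at that count. Monomorphic columns are excluded, so
#' the spectrum sums to the number of segregating sites.
#'
#' @param x polarized `hap_matrix` (or 0/1 matrix taken as polarized).
#' @return Integer vector `S_1..S_{n-1}`.
#' @export
derived_spectrum <- function(x) {
  d <- as_hap_data(x, need_polarized = TRUE)
  n <- nrow(d)
  if (n < 2) stopf("need >= 2 haplotypes")
  tabulate(seg_counts(d), nbins = n - 1L)
}

#' Nucleotide diversity (mean pairwise differences)
#'
#' The average number of differences between two haplotypes, over all
#' pairs: `sum_i 2 i (n-i) S_i / (n (n-1))`. Reported per window (raw
#' count); divide by region length for per-site diversity.
#'
#' @param x `hap_matrix` or 0/1 matrix. Polarization is irrelevant: pi is
#'   symmetric in allele labels.
#' @return Numeric scalar.
#' @export
theta_pi <- function(x) {
  d <- as_hap_data(x)
  n <- nrow(d)
  if (n < 2) stopf("need >= 2 haplotypes")
  cs <- colSums(d)
  sum(cs * (n - cs)) / (n * (n - 1) / 2)
}

#' Watterson's theta
#'
#' `S / a1` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S number of segregating sites (or a `hap_matrix`, from which S
#'   and n are taken).
#' @param n number of haplotypes.
#' @export
theta_w <- function(S, n) {
  if (inherits(S, "hap_matrix")) {
    n <- n_haps(S)
    S <- length(seg_counts(S$data))
  }
  if (n < 2) stopf("need >= 2 haplotypes")
  S / harmonic1(n - 1L)
}

tajima_constants <- function(n) {
  a1 <- harmonic1(n - 1L); a2 <- harmonic2(n - 1L)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Normalized difference between pairwise diversity and Watterson's
#' estimator. Negative values indicate an excess of rare variants.
#' Undefined (NA) when there are no segregating sites.
#'
#' @param x `hap_matrix` or 0/1 matrix; allele labeling does not matter.
#' @export
tajimas_d <- function(x) {
  d <- as_hap_data(x)
  n <- nrow(d)
  if (n < 2) stopf("need >= 2 haplotypes")
  S <- length(seg_counts(d))
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (theta_pi(d) - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Fay and Wu's H and Zeng's theta_L
#'
#' `theta_L = sum_i i S_i / (n-1)` weights the unfolded spectrum by
#' derived copy number; `H = 2 (pi - theta_L)` (equivalently
#' `pi - theta_H` with `theta_H = sum_i 2 i^2 S_i / (n (n-1))`). Strongly
#' negative H marks an excess of high-frequency derived alleles, the
#' hitchhiking signature.
#'
#' @param x polarized `hap_matrix` or 0/1 matrix with 1 = derived.
#' @return list with `theta_l` and `H`.
#' @export
fay_wu_h <- function(x) {
  d <- as_hap_data(x, need_polarized = TRUE)
  n <- nrow(d)
  if (n < 2) stopf("need >= 2 haplotypes")
  i <- seg_counts(d)
  theta_l <- sum(i) / (n - 1)
  list(theta_l = theta_l, H = 2 * (theta_pi(d) - theta_l))
}

# Zeng et al. normalization variance for pi - theta_L
dh_variance <- function(n, S) {
  a1 <- harmonic1(n - 1L); a2 <- harmonic2(n - 1L)
  bn1 <- harmonic2(n)  # sum_{i=1}^{n} 1/i^2
  th <- S / a1
  th2 <- S * (S - 1) / (a1^2 + a2)
  (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
    (9 * n * (n - 1)^2) * th2
}

#' Normalized Fay-Wu H (DH)
#'
#' `(pi - theta_L) / sqrt(Var)` with the variance of Zeng et al. (2006),
#' using `theta_hat = theta_W` and
#' `theta2_hat = S (S-1) / (a1^2 + a2)`. NA when `S = 0`.
#'
#' @param x polarized `hap_matrix` or 0/1 matrix with 1 = derived.
#' @export
normalized_dh <- function(x) {
  d <- as_hap_data(x, need_polarized = TRUE)
  n <- nrow(d)
  if (n < 2) stopf("need >= 2 haplotypes")
  i <- seg_counts(d)
  S <- length(i)
  if (S == 0) return(NA_real_)
  theta_l <- sum(i) / (n - 1)
  v <- dh_variance(n, S)
  if (v <= 0) return(NA_real_)
  (theta_pi(d) - theta_l) / sqrt(v)
}

#' Sliding-window SFS statistics
#'
#' Tiles a region with fixed-size windows and computes, per window, the
#' segregating-site count, pi (raw and per site), Watterson's theta,
#' Tajima's D, theta_L, H and normalized DH on the sites falling inside.
#' Window starts are anchored at the region start and advance by `step`;
#' a region shorter than one window yields a single truncated window
#' (flagged) with a warning. Windows holding fewer than `min_snps` sites
#' report NA for D and DH, whose normalizations are unstable at low S.
#'
#' @param x polarized `hap_matrix` covering the region.
#' @param region single-row region data.frame (0-based half-open).
#' @param window,step window size and step in bp (defaults 5 kb / 500 bp).
#' @param min_snps minimum site count for D/DH (default 10).
#' @param population label copied into the output.
#' @return data.frame, one row per window, columns `chrom, start, end,
#'   population, n_snps, S, pi, pi_per_site, theta_w, theta_w_per_site,
#'   tajimas_d, theta_l, H, DH, truncated`.
#' @export
sliding_windows <- function(x, region, window = 5000L, step = 500L,
                            min_snps = 10L, population = NA_character_) {
  stopifnot(nrow(region) == 1)
  if (!x$polarized) stopf("sliding_windows requires a polarized hap_matrix")
  if (step <= 0 || window < step) stopf("need window >= step > 0")
  len <- region$end - region$start
  truncated <- FALSE
  if (len < window) {
    warnf("region %s shorter (%d bp) than window (%d bp): single truncated window",
          region$label %||% region$chrom, len, window)
    starts <- region$start
    ends <- region$end
    truncated <- TRUE
  } else {
    starts <- seq(region$start, region$end - window, by = step)
    ends <- starts + window
  }
  n <- n_haps(x)
  pos0 <- x$sites$pos - 1L  # to 0-based
  on_chrom <- x$sites$chrom == region$chrom
  cs <- colSums(x$data)
  k <- tajima_constants(n)
  nw <- length(starts)
  n_snps <- S <- integer(nw)
  pi <- tw <- tl <- numeric(nw)
  D <- DH <- rep(NA_real_, nw)
  for (w in seq_len(nw)) {
    j <- which(on_chrom & pos0 >= starts[w] & pos0 < ends[w])
    counts <- cs[j]
    counts <- counts[counts > 0 & counts < n]
    n_snps[w] <- length(j)
    S[w] <- length(counts)
    if (S[w] == 0) next
    pi[w] <- sum(counts * (n - counts)) / (n * (n - 1) / 2)
    tw[w] <- S[w] / k$a1
    tl[w] <- sum(counts) / (n - 1)
    if (S[w] >= min_snps) {
      D[w] <- (pi[w] - tw[w]) / sqrt(k$e1 * S[w] + k$e2 * S[w] * (S[w] - 1))
      v <- dh_variance(n, S[w])
      if (v > 0) DH[w] <- (pi[w] - tl[w]) / sqrt(v)
    }
  }
  wl <- ends - starts
  data.frame(chrom = region$chrom, start = starts, end = ends,
             population = population, n_snps = n_snps, S = S, pi = pi,
             pi_per_site = pi / wl, theta_w = tw, theta_w_per_site = tw / wl,
             tajimas_d = D, theta_l = tl, H = 2 * (pi - tl), DH = DH,
             truncated = truncated)
}

#' Whole-region summary statistics
#'
#' Gene-level counterpart of [sliding_windows()]: one record for the
#' entire region.
#'
#' @inheritParams sliding_windows
#' @export
region_stats <- function(x, region, population = NA_character_) {
  stopifnot(nrow(region) == 1)
  d <- x$data
  n <- nrow(d)
  counts <- seg_counts(d)
  S <- length(counts)
  len <- region$end - region$start
  pi <- if (S) sum(counts * (n - counts)) / (n * (n - 1) / 2) else 0
  tw <- if (S) S / harmonic1(n - 1L) else 0
  fw <- if (x$polarized && S) sum(counts) / (n - 1) else NA_real_
  data.frame(chrom = region$chrom, start = region$start, end = region$end,
             label = region$label, population = population, n_haps = n,
             S = S, pi = pi, pi_per_site = pi / len, theta_w = tw,
             theta_w_per_site = tw / len,
             tajimas_d = if (S) tajimas_d(d) else NA_real_,
             theta_l = fw,
             H = if (!is.na(fw)) 2 * (pi - fw) else NA_real_,
             DH = if (x$polarized && S) normalized_dh(d) else NA_real_)
}
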