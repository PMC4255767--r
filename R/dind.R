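# The DIND test: ratio of intra-allelic nucleotide diversity carried by
# the ancestral vs the derived allele at a focal SNP, measured over a
# fixed window of 40 flanking variants (20 up- and 20 downstream). A
# recent rise of the derived allele compresses the diversity among its
# carriers, inflating i_pi_A / i_pi_D.

#' Derived-allele-frequency bin (100 classes)
#'
#' Right-closed classes `((k-1)/100, k/100]`, `k = 1..100`, indexed
#' `0..99`: DAF 0.98 falls in bin 97, DAF 0.50 in bin 49. DAF 0 and 1 are
#' monomorphic and rejected.
#'
#' @param daf derived allele frequency in `(0, 1)`, vectorized.
#' @return Integer bin index `0..99`.
#' @export
daf_bin <- function(daf) {
  if (any(daf <= 0 | daf >= 1)) stopf("DAF must lie strictly in (0, 1)")
  as.integer(ceiling(daf * 100 - 1e-9)) - 1L
}

# mean pairwise difference count among `rows` over site columns `cols`;
# a class with < 2 haplotypes has no pairs and scores 0 by convention
intra_pi <- function(d, rows, cols) {
  k <- length(rows)
  if (k < 2 || length(cols) == 0) return(0)
  cs <- .colSums(d[rows, cols, drop = FALSE], k, length(cols))
  sum(cs * (k - cs)) / (k * (k - 1) / 2)
}

#' DIND statistic at one focal site
#'
#' Splits the haplotypes by the allele carried at the focal site and
#' measures the mean pairwise difference over the nearest `flank` sites
#' on each side (the focal site itself excluded). Flanking windows are
#' counted in *variants of the loaded site list*, not in bp, and not
#' restricted to sites segregating within the population: a swept
#' population is depleted of local variation by construction, and
#' restricting flankers to within-population SNPs would make the
#' statistic uncomputable exactly where it matters. Sites monomorphic in
#' the population contribute zero pairwise differences to both classes.
#' `dind = i_pi_a / i_pi_d`; when `i_pi_d = 0` the value is
#' sentinel-pending and must be finalized by [resolve_sentinels()] with
#' the maximum over the whole analysis batch plus 20.
#'
#' @param x polarized `hap_matrix` of one population over the full
#'   analyzed region (gene plus flanks).
#' @param focal column index of the focal site in `x`.
#' @param flank flanking variants per side (default 20).
#' @return list `i_pi_a, i_pi_d, dind` (NA when sentinel-pending),
#'   `sentinel` (logical), or `NULL` with attribute-free skip when the
#'   site is ineligible — use [dind_records()] for bulk scanning with
#'   skip bookkeeping.
#' @export
dind_statistic <- function(x, focal, flank = 20L) {
  if (!x$polarized) stopf("DIND requires a polarized hap_matrix")
  d <- x$data
  n <- nrow(d)
  dc <- sum(d[, focal])
  if (dc < 1 || dc > n - 1) stopf("focal site %d is monomorphic", focal)
  if (focal - 1 < flank || ncol(d) - focal < flank)
    stopf("focal site %d has fewer than %d flanking variants on one side",
          focal, flank)
  cols <- c((focal - flank):(focal - 1), (focal + 1):(focal + flank))
  der <- which(d[, focal] == 1L)
  anc <- which(d[, focal] == 0L)
  i_pi_a <- intra_pi(d, anc, cols)
  i_pi_d <- intra_pi(d, der, cols)
  sent <- i_pi_d == 0
  list(i_pi_a = i_pi_a, i_pi_d = i_pi_d,
       dind = if (sent) NA_real_ else i_pi_a / i_pi_d, sentinel = sent)
}

#' DIND records for every eligible site of a region
#'
#' Bulk form of [dind_statistic()]: every site polymorphic in the
#' population with at least `flank` variants of the loaded site list
#' strictly on each side gets a record; ineligible sites are returned
#' with a `skip_reason`. Sentinel-pending records carry `dind = NA`
#' until [resolve_sentinels()] is applied over the full analysis batch
#' (control and test variants together, per population).
#'
#' @inheritParams dind_statistic
#' @param population label copied into the records.
#' @param region_label label copied into the records.
#' @return data.frame with columns `id, chrom, pos, population,
#'   region_label, daf, daf_bin, i_pi_a, i_pi_d, dind, sentinel, rank,
#'   skip_reason`.
#' @export
dind_records <- function(x, flank = 20L, population = NA_character_,
                         region_label = NA_character_) {
  if (!x$polarized) stopf("DIND requires a polarized hap_matrix")
  d <- x$data
  n <- nrow(d)
  p <- ncol(d)
  cs <- colSums(d)
  poly <- cs > 0 & cs < n
  poly_idx <- which(poly)
  res <- data.frame(id = x$sites$id, chrom = x$sites$chrom, pos = x$sites$pos,
                    population = population, region_label = region_label,
                    daf = cs / n, daf_bin = NA_integer_,
                    i_pi_a = NA_real_, i_pi_d = NA_real_, dind = NA_real_,
                    sentinel = FALSE, rank = NA_real_,
                    skip_reason = NA_character_, stringsAsFactors = FALSE)
  res$skip_reason[!poly] <- "monomorphic_in_population"
  for (j in poly_idx) {
    if (j - 1 < flank || p - j < flank) {
      res$skip_reason[j] <- "insufficient_flanking_variants"
      next
    }
    cols <- c((j - flank):(j - 1), (j + 1):(j + flank))
    der <- which(d[, j] == 1L)
    anc <- which(d[, j] == 0L)
    ia <- intra_pi(d, anc, cols)
    id <- intra_pi(d, der, cols)
    res$i_pi_a[j] <- ia
    res$i_pi_d[j] <- id
    res$daf_bin[j] <- daf_bin(res$daf[j])
    if (id == 0) res$sentinel[j] <- TRUE else res$dind[j] <- ia / id
  }
  res
}

#' Finalize sentinel DIND values over an analysis batch
#'
#' Records with `i_pi_d = 0` receive the maximum finite DIND observed
#' over the *whole data set* (control and test variants of the batch,
#' per population) plus 20, so they rank above every finite value.
#'
#' @param records data.frame of DIND records (typically the rbind of
#'   control and test records of one population).
#' @return The records with sentinel `dind` values filled in.
#' @export
resolve_sentinels <- function(records) {
  pend <- records$sentinel & is.na(records$dind)
  if (!any(pend)) return(records)
  finite_max <- suppressWarnings(max(records$dind[!records$sentinel], na.rm = TRUE))
  if (!is.finite(finite_max))
    stopf("batch contains only sentinel-pending DIND values: no finite maximum")
  records$dind[pend] <- finite_max + 20
  records
}

#' Rank DIND records against a DAF-binned control null
#'
#' Assigns each resolved record the percentile rank of its DIND value
#' within its DAF class of the control distribution. Classes that are
#' uncalibrated — too few control values, or a sentinel share of 5% or
#' more (the low-DAF ranges where the 95th percentile cannot be
#' computed) — yield rank NA.
#'
#' @param records resolved DIND records ([resolve_sentinels()]).
#' @param null `empirical_null` built from control DIND records with
#'   identical flank count and sentinel policy.
#' @return The records with the `rank` column filled.
#' @export
dind_scan <- function(records, null) {
  ok <- !is.na(records$dind) & !is.na(records$daf_bin)
  records$rank[ok] <- null_rank(null, records$dind[ok], records$daf_bin[ok])
  records
}
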