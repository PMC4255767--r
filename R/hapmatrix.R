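#' Phased haplotype matrix
#'
#' The central container of the package: a binary matrix with one row per
#' haplotype (two per diploid sample) and one column per biallelic SNP,
#' ordered by position. Before polarization a 1 encodes the ALT allele;
#' after [polarize()] a 1 encodes the *derived* allele.
#'
#' @param data integer/numeric matrix of 0/1, haplotypes x sites.
#' @param sites data.frame with one row per column of `data` and columns
#'   `chrom`, `pos` (1-based, as in VCF), `id`, `ref`, `alt` and
#'   optionally `aa` (ancestral allele annotation, `NA` if unknown).
#' @param hap_ids character vector of haplotype labels, conventionally
#'   `<sample>_1` / `<sample>_2`.
#' @param polarized logical; `TRUE` once 1 == derived allele.
#' @return An object of class `hap_matrix`.
#' @examples
#' hm <- hap_matrix(matrix(c(0, 1, 0, 1, 1, 0), nrow = 2),
#'                  sites = data.frame(chrom = "1", pos = c(10, 20, 30),
#'                                     id = paste0("s", 1:3),
#'                                     ref = "A", alt = "G"),
#'                  hap_ids = c("x_1", "x_2"))
#' n_haps(hm); n_sites(hm)
#' @export
hap_matrix <- function(data, sites, hap_ids = NULL, polarized = FALSE) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (is.null(hap_ids)) hap_ids <- paste0("hap_", seq_len(nrow(data)))
  if (nrow(sites) != ncol(data))
    stopf("sites (%d rows) must match data columns (%d)", nrow(sites), ncol(data))
  if (length(hap_ids) != nrow(data))
    stopf("hap_ids length %d != %d haplotype rows", length(hap_ids), nrow(data))
  if (anyNA(data))
    stopf("hap_matrix does not admit missing entries; drop incomplete sites at load")
  if (!all(data %in% c(0L, 1L)))
    stopf("hap_matrix entries must be 0/1")
  if (!"aa" %in% names(sites)) sites$aa <- NA_character_
  sites$pos <- as.integer(sites$pos)
  # positions must strictly increase within each chromosome
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stopf("site positions not strictly increasing on %s", ch)
  }
  structure(list(data = data, sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 hap_ids = as.character(hap_ids), polarized = isTRUE(polarized)),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes x %d sites (%s)\n",
              n_haps(x), n_sites(x),
              if (x$polarized) "polarized: 1 = derived" else "unpolarized: 1 = alt"))
  if (n_sites(x) > 0)
    cat(sprintf("  %s:%d-%d\n", x$sites$chrom[1], min(x$sites$pos), max(x$sites$pos)))
  invisible(x)
}

#' @rdname hap_matrix
#' @param x a `hap_matrix`.
#' @export
n_haps <- function(x) nrow(x$data)

#' @rdname hap_matrix
#' @export
n_sites <- function(x) ncol(x$data)

#' Derived allele frequency per site
#'
#' @param x a polarized `hap_matrix`.
#' @return Numeric vector of per-site derived allele frequencies.
#' @export
daf <- function(x) {
  if (!x$polarized) stopf("daf() requires a polarized hap_matrix")
  colMeans(x$data)
}

#' Subset a haplotype matrix
#'
#' @param x a `hap_matrix`.
#' @param haps row (haplotype) index or logical/character selector.
#' @param sites column (site) index; `NULL` keeps all.
#' @param drop_monomorphic drop columns monomorphic after row subsetting.
#' @return A `hap_matrix`.
#' @export
hap_subset <- function(x, haps = NULL, sites = NULL, drop_monomorphic = FALSE) {
  d <- x$data
  ids <- x$hap_ids
  if (!is.null(haps)) {
    if (is.character(haps)) haps <- match(haps, ids)
    d <- d[haps, , drop = FALSE]
    ids <- ids[haps]
  }
  st <- x$sites
  if (!is.null(sites)) {
    d <- d[, sites, drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  if (drop_monomorphic && ncol(d) > 0) {
    cs <- colSums(d)
    keep <- cs > 0 & cs < nrow(d)
    d <- d[, keep, drop = FALSE]
    st <- st[keep, , drop = FALSE]
  }
  hap_matrix(d, st, ids, polarized = x$polarized)
}

#' Restrict a haplotype matrix to one population
#'
#' @param x a `hap_matrix` whose `hap_ids` are `<sample>_<1|2>`.
#' @param panel data.frame from [read_panel()].
#' @param population population label to keep.
#' @inheritParams hap_subset
#' @export
hap_population <- function(x, panel, population, drop_monomorphic = FALSE) {
  samples <- panel$sample[panel$population == population]
  if (length(samples) == 0) stopf("population '%s' not present in panel", population)
  sample_of <- sub("_[12]$", "", x$hap_ids)
  keep <- sample_of %in% samples
  if (!any(keep)) stopf("no haplotypes found for population '%s'", population)
  hap_subset(x, haps = which(keep), drop_monomorphic = drop_monomorphic)
}
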