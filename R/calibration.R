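#' Build an empirical null distribution from control records
#'
#' Control-set calibration replaces parametric significance throughout
#' the pipeline: a test value is judged by its percentile among control
#' values of the same allele-frequency class. This constructor routes a
#' stream of control statistics into frequency bins (50 MAF classes for
#' F_ST, 100 DAF classes for DIND, a single pool for window DH) and
#' stores each bin sorted for O(log n) rank lookups.
#'
#' @param values numeric vector of control statistic values.
#' @param bins integer bin index per value (`0..n_classes-1`), or `NULL`
#'   for a single unbinned pool.
#' @param n_classes number of classes (50, 100, or 1).
#' @param statistic label, e.g. `"fst"`, `"dind"`, `"dh_window"`.
#' @param sentinel optional logical vector flagging sentinel-valued
#'   records (DIND `i_pi_d = 0` replacements); used by
#'   [uncalibrated_bins()].
#' @param min_bin_count bins holding fewer control values than this are
#'   unusable and yield rank NA (default 20).
#' @param comparison free-text provenance (population or pair).
#' @return An object of class `empirical_null`.
#' @export
build_null <- function(values, bins = NULL, n_classes = if (is.null(bins)) 1L else max(bins) + 1L,
                       statistic = "stat", sentinel = NULL, min_bin_count = 20L,
                       comparison = NA_character_) {
  keep <- !is.na(values)
  values <- values[keep]
  if (length(values) == 0) stopf("empty control stream: cannot build a null")
  if (is.null(bins)) bins <- rep(0L, length(values)) else {
    bins <- as.integer(bins)[keep]
    if (anyNA(bins) || any(bins < 0 | bins >= n_classes))
      stopf("bin indices must lie in 0..%d", n_classes - 1L)
  }
  if (is.null(sentinel)) sentinel <- rep(FALSE, length(values)) else
    sentinel <- as.logical(sentinel)[keep]
  f <- factor(bins, levels = 0:(n_classes - 1L))
  bin_values <- lapply(split(values, f), sort)
  sentinel_counts <- vapply(split(sentinel, f), sum, integer(1))
  fin <- values[!sentinel]
  structure(list(statistic = statistic, n_classes = as.integer(n_classes),
                 bins = bin_values, sentinel_counts = sentinel_counts,
                 min_bin_count = as.integer(min_bin_count),
                 max_finite = if (length(fin)) max(fin) else NA_real_,
                 n_values = length(values), comparison = comparison),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("empirical_null[%s]: %d values in %d class(es); %d uncalibrated\n",
              x$statistic, x$n_values, x$n_classes,
              length(uncalibrated_bins(x))))
  invisible(x)
}

#' Percentile rank of a value in a control array
#'
#' `rank = (# control values strictly below) / (# control values)`; tied
#' control values count as not-below, the conservative convention shared
#' by all statistics in the package.
#'
#' @param value numeric vector of observed values.
#' @param controls numeric vector of control values (need not be sorted).
#' @return Ranks in `[0, 1]`; NA if `controls` is empty.
#' @export
percentile_rank <- function(value, controls) {
  controls <- sort(controls[!is.na(controls)])
  if (length(controls) == 0) return(rep(NA_real_, length(value)))
  findInterval(value, controls, left.open = TRUE) / length(controls)
}

#' Uncalibrated frequency classes of a null
#'
#' A class cannot discriminate outliers when its 95th percentile is
#' itself the sentinel value, i.e. when 5% or more of its control values
#' are sentinels (boundary inclusive), or when it holds fewer than
#' `min_bin_count` values. Test variants in these classes get rank NA;
#' for DIND this reproduces the low-DAF ranges in which the statistic is
#' not computed.
#'
#' @param null an `empirical_null`.
#' @param sentinel_frac sentinel share at or above which a bin is
#'   uncalibrated (default 0.05).
#' @return Integer vector of 0-based bin indices.
#' @export
uncalibrated_bins <- function(null, sentinel_frac = 0.05) {
  counts <- vapply(null$bins, length, integer(1))
  frac <- ifelse(counts > 0, null$sentinel_counts / counts, 1)
  which(counts < null$min_bin_count | frac >= sentinel_frac) - 1L
}

#' Rank observed values against an empirical null
#'
#' @param null an `empirical_null`.
#' @param values observed statistic values.
#' @param bins 0-based bin index per value (recycled if length 1).
#' @return Percentile ranks; NA for values in uncalibrated bins.
#' @export
null_rank <- function(null, values, bins = 0L) {
  if (length(bins) == 1L) bins <- rep(as.integer(bins), length(values))
  bad <- uncalibrated_bins(null)
  out <- rep(NA_real_, length(values))
  for (b in unique(bins)) {
    sel <- which(bins == b)
    if (b %in% bad || b < 0 || b >= null$n_classes) next
    arr <- null$bins[[b + 1L]]
    out[sel] <- findInterval(values[sel], arr, left.open = TRUE) / length(arr)
  }
  out
}

#' Serialize / restore an empirical null
#'
#' The TSV cache has a commented header naming the statistic and binning
#' and columns `bin, value, sentinel`; reloading reproduces identical
#' percentile lookups.
#'
#' @param null an `empirical_null`.
#' @param path TSV path.
#' @export
null_to_tsv <- function(null, path) {
  bins <- rep(0:(null$n_classes - 1L), vapply(null$bins, length, integer(1)))
  values <- unlist(null$bins, use.names = FALSE)
  # sentinel flags are stored per bin as counts over the top of the sorted
  # array (sentinels are by construction the largest values in a bin)
  sentinel <- unlist(lapply(seq_along(null$bins), function(i) {
    k <- length(null$bins[[i]])
    s <- null$sentinel_counts[i]
    c(rep(FALSE, k - s), rep(TRUE, s))
  }), use.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hapsweep empirical_null statistic=%s n_classes=%d min_bin_count=%d comparison=%s",
                     null$statistic, null$n_classes, null$min_bin_count,
                     null$comparison), con)
  write.table(data.frame(bin = bins, value = values, sentinel = sentinel),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname null_to_tsv
#' @param path TSV written by [null_to_tsv()].
#' @export
null_from_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  d <- read.delim(path, comment.char = "#")
  build_null(d$value, bins = d$bin, n_classes = as.integer(kv[["n_classes"]]),
             statistic = kv[["statistic"]], sentinel = d$sentinel,
             min_bin_count = as.integer(kv[["min_bin_count"]]),
             comparison = kv[["comparison"]])
}

#' Fifth-percentile threshold for window DH
#'
#' Empirical q-quantile (linear interpolation between order statistics,
#' `stats::quantile` type 7) of the control windows' normalized DH.
#' Windows of a test region falling below the threshold are flagged as
#' confirmatory sweep signals.
#'
#' @param control_dh numeric vector of control-window DH values (NA
#'   dropped); at least 100 required.
#' @param q quantile (default 0.05).
#' @export
dh_window_threshold <- function(control_dh, q = 0.05) {
  control_dh <- control_dh[!is.na(control_dh)]
  if (length(control_dh) < 100)
    stopf("need >= 100 control windows for a stable threshold (got %d)",
          length(control_dh))
  unname(quantile(control_dh, probs = q, type = 7))
}

#' Combined-evidence positive-selection caller
#'
#' A region is called a selection target in a population when two
#' statistics from *different* feature families reach the empirical rank
#' threshold there on the *same variant*: per-SNP F_ST (differentiation;
#' a pairwise comparison credits both of its populations) and DIND
#' (intra-allelic diversity). Threshold comparison is inclusive (`>=`).
#'
#' Frequency-spectrum evidence is reported but never primary: window DH
#' below the control fifth percentile and a gene-level Tajima's D in the
#' low control tail (`rank <= 1 - threshold`) are attached as
#' confirmatory annotations. Region-level pairing of a gene statistic
#' with any site-level hit would, under neutrality, call a region
#' whenever its gene-level D lands in the 5% tail and any of its many
#' correlated variants fires one site statistic — far above the intended
#' false-positive rarity — so the verdict requires the same-variant
#' site-level pair.
#'
#' @param fst_records data.frame from [fst_scan()] with an added
#'   `region_label` column.
#' @param dind_records data.frame from [dind_scan()] with `region_label`
#'   and `population`.
#' @param gene_stats optional data.frame with `region_label, population,
#'   rank` of gene-level Tajima's D against the control distribution.
#' @param dh_windows optional data.frame of window records with
#'   `region_label, population, start, end, DH`.
#' @param dh_threshold numeric DH threshold from [dh_window_threshold()],
#'   or a named vector per population.
#' @param threshold rank threshold (default 0.95).
#' @return data.frame, one row per region x population, with `verdict`,
#'   supporting-variant summary, confirmatory DH window count, and a
#'   human-readable `rationale`.
#' @export
combined_caller <- function(fst_records = NULL, dind_records = NULL,
                            gene_stats = NULL, dh_windows = NULL,
                            dh_threshold = NULL, threshold = 0.95) {
  pops <- unique(c(dind_records$population, gene_stats$population,
                   if (!is.null(fst_records) && nrow(fst_records))
                     unlist(strsplit(unique(fst_records$comparison), "/", fixed = TRUE))))
  regions <- unique(c(fst_records$region_label, dind_records$region_label,
                      gene_stats$region_label))
  out <- list()
  for (reg in regions) for (pop in pops) {
    d_hit <- f_hit <- character(0)
    d_rec <- f_rec <- NULL
    if (!is.null(dind_records)) {
      d_rec <- dind_records[dind_records$region_label == reg &
                              dind_records$population == pop &
                              !is.na(dind_records$rank) &
                              dind_records$rank >= threshold, , drop = FALSE]
      d_hit <- unique(d_rec$id)
    }
    if (!is.null(fst_records)) {
      in_pair <- vapply(strsplit(fst_records$comparison, "/", fixed = TRUE),
                        function(p) pop %in% p, logical(1))
      f_rec <- fst_records[fst_records$region_label == reg & in_pair &
                             !is.na(fst_records$rank) &
                             fst_records$rank >= threshold, , drop = FALSE]
      f_hit <- unique(f_rec$id)
    }
    sfs_hit <- FALSE
    if (!is.null(gene_stats)) {
      g <- gene_stats[gene_stats$region_label == reg &
                        gene_stats$population == pop, , drop = FALSE]
      sfs_hit <- nrow(g) > 0 && any(!is.na(g$rank) & g$rank <= 1 - threshold)
    }
    joint <- intersect(d_hit, f_hit)
    verdict <- length(joint) > 0
    n_dh <- NA_integer_
    if (!is.null(dh_windows) && !is.null(dh_threshold)) {
      thr <- if (length(dh_threshold) > 1) dh_threshold[[pop]] else dh_threshold
      w <- dh_windows[dh_windows$region_label == reg &
                        dh_windows$population == pop, , drop = FALSE]
      n_dh <- sum(!is.na(w$DH) & w$DH < thr)
    }
    rationale <- if (length(joint)) {
      sprintf("variant(s) %s reach rank >= %.2f for both DIND and F_ST in %s",
              paste(joint, collapse = ","), threshold, pop)
    } else "no variant reaches the rank threshold in two feature families"
    if (verdict && !is.na(n_dh) && n_dh > 0)
      rationale <- paste0(rationale, sprintf("; confirmed by %d DH window(s) below the control fifth percentile", n_dh))
    if (verdict && sfs_hit)
      rationale <- paste0(rationale, "; gene-level Tajima's D in the low control tail")
    out[[length(out) + 1L]] <- data.frame(
      region_label = reg, population = pop, verdict = verdict,
      n_dind_hits = length(d_hit), n_fst_hits = length(f_hit),
      sfs_hit = sfs_hit,
      support_variants = paste(joint, collapse = ","),
      n_dh_confirm = n_dh, rationale = rationale,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
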