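#' Scan configuration
#'
#' Bundles the file paths and parameters of a full scan. The defaults are
#' the scan's canonical values: 5-kb DH windows stepping by 500 bp, 40
#' DIND flanking variants (20 per side), 50 MAF classes, 100 DAF
#' classes, rank threshold 0.95, DH fifth percentile, and 30-kb region
#' flanks per side.
#'
#' @param vcf phased VCF path.
#' @param panel panel TSV path ([read_panel()]).
#' @param test_bed BED of regions to scan.
#' @param control_bed BED of control regions building the empirical
#'   nulls; when a single BED holds both, rows labelled `control` /
#'   `test` in column 4 are split automatically (pass it as both
#'   arguments).
#' @param populations population labels to analyze.
#' @param comparisons character vector of `"A/B"` population pairs for
#'   F_ST; default: all pairs of `populations`.
#' @param window,step DH sliding-window size and step (bp).
#' @param flank_variants DIND flanking variants per side.
#' @param rank_threshold combined-caller rank threshold.
#' @param dh_quantile control quantile flagging confirmatory DH windows.
#' @param region_flank bp added on each side of every test region before
#'   site-level statistics (0 when regions already include flanks, as in
#'   simulated cohorts).
#' @param min_snps minimum S for window D/DH.
#' @param min_bin_count minimum control values per usable frequency bin.
#' @param out_dir optional directory for TSV/BED reports.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(vcf, panel, test_bed, control_bed,
                        populations, comparisons = NULL,
                        window = 5000L, step = 500L, flank_variants = 20L,
                        rank_threshold = 0.95, dh_quantile = 0.05,
                        region_flank = 30000L, min_snps = 10L,
                        min_bin_count = 20L, out_dir = NULL) {
  if (is.null(comparisons) && length(populations) > 1) {
    cmb <- utils::combn(populations, 2)
    comparisons <- paste(cmb[1, ], cmb[2, ], sep = "/")
  }
  stopifnot(window >= step, step > 0, flank_variants > 0,
            rank_threshold > 0, rank_threshold <= 1, region_flank >= 0)
  structure(list(vcf = vcf, panel = panel, test_bed = test_bed,
                 control_bed = control_bed, populations = populations,
                 comparisons = comparisons, window = as.integer(window),
                 step = as.integer(step),
                 flank_variants = as.integer(flank_variants),
                 rank_threshold = rank_threshold, dh_quantile = dh_quantile,
                 region_flank = as.integer(region_flank),
                 min_snps = as.integer(min_snps),
                 min_bin_count = as.integer(min_bin_count),
                 out_dir = out_dir),
            class = "scan_config")
}

split_roles <- function(regs) {
  if (all(is.na(regs$label))) return(NULL)
  list(control = regs[regs$label == "control", , drop = FALSE],
       test = regs[regs$label != "control", , drop = FALSE])
}

# site-column indices of a region within the full matrix
region_cols <- function(hm, reg) {
  which(hm$sites$chrom == reg$chrom &
          hm$sites$pos >= reg$start + 1L & hm$sites$pos <= reg$end)
}

#' Run the full selection scan
#'
#' Orchestrates every stage on one cohort: load and polarize the VCF,
#' compute gene-level SFS statistics, sliding-window DH, per-SNP F_ST and
#' DIND for control and test regions, build the empirical nulls from the
#' controls, rank the test records, and apply the combined-evidence
#' caller. Deterministic given its inputs.
#'
#' @param config a [scan_config()].
#' @param verbose log per-stage counts.
#' @return list with elements `calls` (combined-caller verdicts), `fst`,
#'   `dind`, `gene_stats`, `windows` (test-region records), `dh_threshold`
#'   (per population), and `nulls`.
#' @export
run_scan <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "scan_config"))
  panel <- read_panel(config$panel)
  missing_pop <- setdiff(config$populations, unique(panel$population))
  if (length(missing_pop))
    stopf("population '%s' not present in panel", missing_pop[1])
  test_regs <- read_regions_bed(config$test_bed)
  ctrl_regs <- read_regions_bed(config$control_bed)
  if (identical(config$test_bed, config$control_bed)) {
    roles <- split_roles(test_regs)
    if (is.null(roles)) stopf("shared BED needs control/test labels in column 4")
    test_regs <- roles$test
    ctrl_regs <- roles$control
  }
  if (config$region_flank > 0) {
    test_regs_f <- flank_region(test_regs, config$region_flank)
    ctrl_regs_f <- flank_region(ctrl_regs, config$region_flank)
  } else {
    test_regs_f <- test_regs
    ctrl_regs_f <- ctrl_regs
  }
  hm0 <- read_phased_vcf(config$vcf, panel = panel,
                         populations = config$populations, verbose = verbose)
  hm <- polarize(hm0, verbose = verbose)
  if (verbose)
    message(sprintf("run_scan: %d polarized sites, %d haplotypes, %d test + %d control regions",
                    n_sites(hm), n_haps(hm), nrow(test_regs), nrow(ctrl_regs)))

  pop_hm <- lapply(setNames(config$populations, config$populations),
                   function(p) hap_population(hm, panel, p))

  per_region <- function(regs, regs_f, role) {
    gene <- list(); win <- list(); dindr <- list(); fstr <- list()
    for (k in seq_len(nrow(regs))) {
      reg <- regs[k, , drop = FALSE]
      reg_f <- regs_f[k, , drop = FALSE]
      lab <- if (is.na(reg$label) || reg$label %in% c("control", "test"))
        sprintf("%s:%d-%d", reg$chrom, reg$start, reg$end) else reg$label
      for (p in config$populations) {
        sub <- hap_subset(pop_hm[[p]], sites = region_cols(pop_hm[[p]], reg_f))
        # gene-level statistics on the unflanked region only
        g <- region_stats(hap_subset(pop_hm[[p]],
                                     sites = region_cols(pop_hm[[p]], reg)),
                          reg, population = p)
        g$region_label <- lab
        gene[[length(gene) + 1L]] <- g
        w <- suppressWarnings(sliding_windows(sub, reg_f, config$window,
                                              config$step, config$min_snps, p))
        w$region_label <- lab
        win[[length(win) + 1L]] <- w
        d <- dind_records(sub, flank = config$flank_variants, population = p,
                          region_label = lab)
        dindr[[length(dindr) + 1L]] <- d
      }
      for (cmp in config$comparisons) {
        pq <- strsplit(cmp, "/", fixed = TRUE)[[1]]
        sub <- hap_subset(hm, sites = region_cols(hm, reg_f))
        f <- fst_scan(sub, panel, pq[1], pq[2])
        if (nrow(f)) {
          f$region_label <- lab
          fstr[[length(fstr) + 1L]] <- f
        }
      }
    }
    list(gene = do.call(rbind, gene), win = do.call(rbind, win),
         dind = do.call(rbind, dindr), fst = do.call(rbind, fstr))
  }

  ctrl <- per_region(ctrl_regs, ctrl_regs_f, "control")
  test <- per_region(test_regs, test_regs_f, "test")

  # --- DIND: batch-global sentinel resolution (control + test, per pop)
  nulls <- list()
  dind_out <- list()
  for (p in config$populations) {
    batch <- rbind(ctrl$dind[ctrl$dind$population == p, , drop = FALSE],
                   test$dind[test$dind$population == p, , drop = FALSE])
    batch$role <- rep(c("control", "test"),
                      c(sum(ctrl$dind$population == p),
                        sum(test$dind$population == p)))
    batch <- resolve_sentinels(batch)
    cb <- batch[batch$role == "control" & !is.na(batch$dind), , drop = FALSE]
    if (nrow(cb) == 0) stopf("no control DIND values for population %s", p)
    nulls[[paste0("dind_", p)]] <- build_null(
      cb$dind, bins = cb$daf_bin, n_classes = 100L, statistic = "dind",
      sentinel = cb$sentinel, min_bin_count = config$min_bin_count,
      comparison = p)
    tb <- batch[batch$role == "test", , drop = FALSE]
    dind_out[[p]] <- dind_scan(tb, nulls[[paste0("dind_", p)]])
  }
  dind_out <- do.call(rbind, dind_out)

  # --- F_ST: MAF-binned nulls per comparison
  fst_out <- list()
  for (cmp in config$comparisons %||% character(0)) {
    cf <- ctrl$fst[ctrl$fst$comparison == cmp, , drop = FALSE]
    if (nrow(cf) == 0) stopf("no control F_ST values for comparison %s", cmp)
    nulls[[paste0("fst_", cmp)]] <- build_null(
      cf$fst, bins = cf$maf_bin, n_classes = 50L, statistic = "fst",
      min_bin_count = config$min_bin_count, comparison = cmp)
    tf <- test$fst[test$fst$comparison == cmp, , drop = FALSE]
    tf$rank <- null_rank(nulls[[paste0("fst_", cmp)]], tf$fst, tf$maf_bin)
    fst_out[[cmp]] <- tf
  }
  fst_out <- do.call(rbind, fst_out)

  # --- gene-level Tajima's D vs the control gene distribution
  gene_out <- test$gene
  gene_out$rank <- NA_real_
  for (p in config$populations) {
    cg <- ctrl$gene$tajimas_d[ctrl$gene$population == p]
    cg <- cg[!is.na(cg)]
    sel <- gene_out$population == p & !is.na(gene_out$tajimas_d)
    if (length(cg) >= config$min_bin_count && any(sel))
      gene_out$rank[sel] <- percentile_rank(gene_out$tajimas_d[sel], cg)
  }

  # --- DH fifth-percentile thresholds from control windows
  dh_thr <- sapply(setNames(config$populations, config$populations),
                   function(p) {
                     v <- ctrl$win$DH[ctrl$win$population == p]
                     v <- v[!is.na(v)]
                     if (length(v) >= 100) dh_window_threshold(v, config$dh_quantile)
                     else NA_real_
                   })

  calls <- combined_caller(fst_records = fst_out, dind_records = dind_out,
                           gene_stats = gene_out, dh_windows = test$win,
                           dh_threshold = dh_thr,
                           threshold = config$rank_threshold)
  res <- list(calls = calls, fst = fst_out, dind = dind_out,
              gene_stats = gene_out, windows = test$win,
              dh_threshold = dh_thr, nulls = nulls)
  if (!is.null(config$out_dir)) write_scan_reports(res, config)
  if (verbose)
    message(sprintf("run_scan: %d region x population verdicts, %d positive",
                    nrow(calls), sum(calls$verdict)))
  res
}

write_scan_reports <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# hapsweep %s scan window=%d step=%d flank_variants=%d rank_threshold=%g",
                 as.character(utils::packageVersion("hapsweep")),
                 config$window, config$step, config$flank_variants,
                 config$rank_threshold)
  wr <- function(d, f) {
    path <- file.path(config$out_dir, f)
    con <- file(path, "w")
    writeLines(hdr, con)
    write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wr(res$calls, "calls.tsv")
  wr(res$fst, "fst.tsv")
  wr(res$dind, "dind.tsv")
  wr(res$gene_stats, "gene_stats.tsv")
  wr(res$windows, "windows.tsv")
  for (nm in names(res$nulls))
    null_to_tsv(res$nulls[[nm]], file.path(config$out_dir, paste0("null_", gsub("/", "_", nm), ".tsv")))
  # confirmatory windows as BED, per population threshold
  conf <- do.call(rbind, lapply(names(res$dh_threshold), function(p) {
    thr <- res$dh_threshold[[p]]
    if (is.na(thr)) return(NULL)
    w <- res$windows[res$windows$population == p & !is.na(res$windows$DH), , drop = FALSE]
    w[w$DH < thr, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (!is.null(conf) && nrow(conf))
    write_regions_bed(region(conf$chrom, conf$start, conf$end, "low_DH"),
                      file.path(config$out_dir, "dh_windows.bed"))
  invisible(config$out_dir)
}
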