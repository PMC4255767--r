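# Coalescent generator of phased, polarized SNP haplotypes under an
# infinite-sites model without intra-locus recombination. Three
# scenarios: neutral equilibrium, a symmetric two-deme island model, and
# a hard-sweep approximation in which the coalescent times internal to
# the derived-carrier subtree are compressed by a factor c (c -> 0 gives
# a star genealogy, i.e. i_pi_D -> 0). Loci default to 70 kb, the extent
# of a gene analyzed with 30-kb flanks.

# ---- genealogy machinery ---------------------------------------------

# standard n-coalescent on the given leaf labels; returns closed branches
# as list(sets = list of leaf-index vectors, lens = numeric). time_scale
# multiplies every exponential waiting time (the sweep compression).
coalesce_tree <- function(leaves, time_scale = 1) {
  k <- length(leaves)
  lineages <- as.list(leaves)
  blen <- numeric(k)
  sets <- vector("list", 2L * (k - 1L))
  lens <- numeric(2L * (k - 1L))
  nb <- 0L
  while (k > 1) {
    blen <- blen + rexp(1, k * (k - 1) / 2) * time_scale
    pair <- sample.int(k, 2L)
    i <- pair[1]; j <- pair[2]
    sets[[nb + 1L]] <- lineages[[i]]; lens[nb + 1L] <- blen[i]
    sets[[nb + 2L]] <- lineages[[j]]; lens[nb + 2L] <- blen[j]
    nb <- nb + 2L
    lineages[[i]] <- c(lineages[[i]], lineages[[j]])
    blen[i] <- 0
    lineages[[j]] <- lineages[[k]]
    blen[j] <- blen[k]
    length(lineages) <- k - 1L
    blen <- blen[seq_len(k - 1L)]
    k <- k - 1L
  }
  list(sets = sets[seq_len(nb)], lens = lens[seq_len(nb)],
       root = lineages[[1]])
}

# two-deme structured coalescent, symmetric migration at rate M/2 per
# lineage (M = 4Nm); coalescence only within demes.
coalesce_island <- function(n_per_deme, migration) {
  if (migration <= 0) stopf("island model requires migration > 0")
  n <- 2L * n_per_deme
  lineages <- as.list(seq_len(n))
  deme <- rep(c(1L, 2L), each = n_per_deme)
  blen <- numeric(n)
  sets <- list(); lens <- numeric(0)
  k <- n
  while (k > 1) {
    k1 <- sum(deme == 1L); k2 <- k - k1
    rc1 <- k1 * (k1 - 1) / 2
    rc2 <- k2 * (k2 - 1) / 2
    rm <- k * migration / 2
    tot <- rc1 + rc2 + rm
    blen <- blen + rexp(1, tot)
    u <- runif(1) * tot
    if (u < rc1 + rc2) {
      d <- if (u < rc1) 1L else 2L
      idx <- which(deme == d)
      pair <- idx[sample.int(length(idx), 2L)]
      i <- pair[1]; j <- pair[2]
      sets[[length(sets) + 1L]] <- lineages[[i]]; lens <- c(lens, blen[i])
      sets[[length(sets) + 1L]] <- lineages[[j]]; lens <- c(lens, blen[j])
      lineages[[i]] <- c(lineages[[i]], lineages[[j]])
      blen[i] <- 0
      lineages[[j]] <- lineages[[k]]
      blen[j] <- blen[k]
      deme[j] <- deme[k]
      length(lineages) <- k - 1L
      blen <- blen[seq_len(k - 1L)]
      deme <- deme[seq_len(k - 1L)]
      k <- k - 1L
    } else {
      i <- sample.int(k, 1L)
      deme[i] <- 3L - deme[i]
    }
  }
  list(sets = sets, lens = lens, root = lineages[[1]])
}

# drop mutations on a branch set and build the 0/1 matrix (1 = derived)
mutate_branches <- function(branches, n, theta, locus_length,
                            extra_sets = list(), extra_pos = integer(0)) {
  total_len <- sum(branches$lens)
  n_mut <- rpois(1, theta / 2 * total_len)
  carried <- list()
  if (n_mut > 0) {
    which_branch <- sample.int(length(branches$lens), n_mut, replace = TRUE,
                               prob = branches$lens)
    carried <- branches$sets[which_branch]
  }
  avail <- setdiff(seq_len(locus_length), extra_pos)
  if (length(avail) < length(carried))
    stopf("locus_length %d too small for %d mutations", locus_length, length(carried))
  pos <- sample(avail, length(carried))
  pos <- c(pos, extra_pos)
  carried <- c(carried, extra_sets)
  o <- order(pos)
  pos <- pos[o]; carried <- carried[o]
  m <- matrix(0L, nrow = n, ncol = length(pos))
  for (s in seq_along(carried)) m[carried[[s]], s] <- 1L
  list(data = m, pos = as.integer(pos))
}

# random ref/alt/ancestral assignment so the emitted VCF is unpolarized
make_sites <- function(chrom, pos) {
  if (length(pos) == 0)
    return(data.frame(chrom = character(0), pos = integer(0), id = character(0),
                      ref = character(0), alt = character(0), aa = character(0),
                      stringsAsFactors = FALSE))
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length(pos), replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(bases, a), 1L), character(1))
  anc_is_ref <- runif(length(pos)) < 0.5
  data.frame(chrom = chrom, pos = pos,
             id = sprintf("%s_p%d", chrom, pos),
             ref = ifelse(anc_is_ref, anc, der),
             alt = ifelse(anc_is_ref, der, anc),
             aa = anc, stringsAsFactors = FALSE)
}

finish_matrix <- function(mut, chrom, n, locus_length) {
  hm <- hap_matrix(mut$data, make_sites(chrom, mut$pos),
                   hap_ids = as.vector(rbind(paste0("s", seq_len(n / 2), "_1"),
                                             paste0("s", seq_len(n / 2), "_2"))),
                   polarized = TRUE)
  attr(hm, "locus_length") <- as.integer(locus_length)
  hm
}

# ---- public scenarios ------------------------------------------------

#' Simulate a neutral-equilibrium locus
#'
#' Standard n-coalescent (successive exponential coalescences at rate
#' k(k-1)/2 in units of 4N generations) with Poisson(theta/2 * L)
#' mutations placed on branches proportionally to length; each mutation
#' is a unique biallelic site with known derived allele, at a distinct
#' integer position uniform on the locus.
#'
#' @param n haplotypes (even, so the matrix maps onto diploid samples).
#' @param theta population-scaled mutation rate 4Nu per locus.
#' @param locus_length locus size in bp (default 70 kb: a gene plus
#'   30-kb flanks).
#' @param chrom contig name for the emitted sites.
#' @param seed optional integer; same seed, same output.
#' @return Polarized `hap_matrix` whose `sites$aa` records the true
#'   ancestral allele.
#' @export
simulate_neutral <- function(n, theta, locus_length = 70000L,
                             chrom = "locus_1", seed = NULL) {
  if (n < 2) stopf("need n >= 2")
  if (n %% 2L != 0L) stopf("n must be even (diploid samples)")
  if (!is.null(seed)) set.seed(seed)
  tree <- coalesce_tree(seq_len(n))
  mut <- mutate_branches(tree, n, theta, locus_length)
  finish_matrix(mut, chrom, n, locus_length)
}

#' Simulate a two-deme island-model locus
#'
#' Structured coalescent with two demes of equal size, symmetric
#' migration at scaled rate `migration/2` per lineage (`migration` =
#' 4Nm), and coalescence only within demes. Haplotypes `1..n_per_deme`
#' belong to deme 1. The returned matrix carries attribute `demes`.
#'
#' @param n_per_deme haplotypes per deme (even).
#' @param migration scaled migration rate 4Nm, > 0.
#' @inheritParams simulate_neutral
#' @export
simulate_island <- function(n_per_deme, theta, migration,
                            locus_length = 70000L, chrom = "locus_1",
                            seed = NULL) {
  if (n_per_deme < 2) stopf("need >= 2 haplotypes per deme")
  if (n_per_deme %% 2L != 0L) stopf("n_per_deme must be even")
  if (migration <= 0)
    stopf("migration = 0 with lineages in both demes: no common ancestor")
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_deme
  tree <- coalesce_island(n_per_deme, migration)
  mut <- mutate_branches(tree, n, theta, locus_length)
  hm <- finish_matrix(mut, chrom, n, locus_length)
  attr(hm, "demes") <- rep(c(1L, 2L), each = n_per_deme)
  hm
}

#' Simulate a hard-sweep locus
#'
#' Approximates the post-sweep genealogy: the `round(sweep_daf * n)`
#' haplotypes carrying the focal derived allele (rows `1..n_d`) form a
#' clade whose internal coalescent times are multiplied by `compression`
#' before mutation placement, compressing intra-derived diversity;
#' the ancestral class and the deep genealogy joining the derived-clade
#' root to it remain neutral. The focal mutation itself is planted at
#' the locus midpoint. `compression = 1` recovers a neutral genealogy
#' conditioned on the focal-allele clade.
#'
#' @param sweep_daf target derived frequency of the focal allele, in
#'   (0, 1); `sweep_daf * n` must be >= 2.
#' @param compression c in (0, 1]: scaling of the derived-subtree times.
#' @inheritParams simulate_neutral
#' @return Polarized `hap_matrix` with attributes `focal` (column index
#'   of the planted site) and `focal_id`.
#' @export
simulate_sweep <- function(n, theta, sweep_daf, compression,
                           locus_length = 70000L, chrom = "locus_1",
                           seed = NULL) {
  if (n %% 2L != 0L) stopf("n must be even")
  if (sweep_daf <= 0 || sweep_daf >= 1) stopf("sweep_daf must lie in (0, 1)")
  if (compression <= 0 || compression > 1) stopf("compression must lie in (0, 1]")
  n_d <- round(sweep_daf * n)
  if (n_d < 2) stopf("sweep_daf * n must be >= 2")
  if (n_d > n - 1) n_d <- n - 1L
  if (!is.null(seed)) set.seed(seed)
  derived <- seq_len(n_d)
  sub <- coalesce_tree(derived, time_scale = compression)
  # deep phase: the derived-clade root competes with ancestral leaves
  deep_leaves <- c(list(sub$root), as.list((n_d + 1L):n))
  k <- length(deep_leaves)
  lineages <- deep_leaves
  blen <- numeric(k)
  sets <- sub$sets; lens <- sub$lens
  while (k > 1) {
    blen <- blen + rexp(1, k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    i <- pair[1]; j <- pair[2]
    sets[[length(sets) + 1L]] <- lineages[[i]]; lens <- c(lens, blen[i])
    sets[[length(sets) + 1L]] <- lineages[[j]]; lens <- c(lens, blen[j])
    lineages[[i]] <- c(lineages[[i]], lineages[[j]])
    blen[i] <- 0
    lineages[[j]] <- lineages[[k]]
    blen[j] <- blen[k]
    length(lineages) <- k - 1L
    blen <- blen[seq_len(k - 1L)]
    k <- k - 1L
  }
  focal_pos <- as.integer(locus_length %/% 2L)
  mut <- mutate_branches(list(sets = sets, lens = lens), n, theta,
                         locus_length, extra_sets = list(derived),
                         extra_pos = focal_pos)
  hm <- finish_matrix(mut, chrom, n, locus_length)
  attr(hm, "focal") <- match(focal_pos, hm$sites$pos)
  attr(hm, "focal_id") <- hm$sites$id[attr(hm, "focal")]
  hm
}

# ---- cohorts ---------------------------------------------------------

#' Simulate a multi-locus cohort
#'
#' Draws independent loci, each on its own contig `locus_<i>`, with a
#' per-locus RNG stream derived from `(seed, i)` so any locus is
#' reproducible in isolation. Scenario `"sweep"` plants its focal allele
#' so that all carriers fall in the first `n_carrier` haplotypes, which a
#' two-population panel maps onto population 1.
#'
#' @param n_loci number of loci.
#' @param scenario `"neutral"`, `"island"` or `"sweep"`.
#' @param n total haplotypes (per deme for `"island"`).
#' @param theta per-locus 4Nu.
#' @param seed master seed.
#' @param ... scenario parameters passed through (`migration`,
#'   `sweep_daf`, `compression`, `locus_length`).
#' @param locus_names contig names, one per locus (default
#'   `locus_1..locus_<n_loci>`); supply distinct names when combining
#'   several cohorts into one VCF.
#' @return list of `hap_matrix` objects named by `locus_names`.
#' @export
simulate_cohort <- function(n_loci, scenario = c("neutral", "island", "sweep"),
                            n, theta, seed = 1L, ...,
                            locus_names = sprintf("locus_%d", seq_len(n_loci))) {
  scenario <- match.arg(scenario)
  stopifnot(length(locus_names) == n_loci, !anyDuplicated(locus_names))
  fn <- switch(scenario, neutral = simulate_neutral,
               island = function(n, theta, ...) simulate_island(n_per_deme = n, theta = theta, ...),
               sweep = simulate_sweep)
  out <- lapply(seq_len(n_loci), function(i)
    fn(n, theta, chrom = locus_names[i], seed = child_seed(seed, i), ...))
  names(out) <- locus_names
  out
}

#' Write a simulated cohort to standard formats
#'
#' Emits one phased VCF (GT + true-ancestral `AA` INFO tag) covering all
#' loci, a sample-to-population panel TSV, a BED of locus regions
#' labelled control/test, and a truth TSV recording scenario parameters
#' and planted focal variants.
#'
#' @param matrices named list from [simulate_cohort()] (all loci must
#'   share the haplotype count).
#' @param out_dir output directory (created).
#' @param populations character vector of population labels; haplotypes
#'   are split into equal consecutive blocks, two per sample.
#' @param test_loci names (or indices) of loci labelled `test` in the
#'   BED; the rest are `control`.
#' @param truth optional data.frame of extra per-locus truth columns.
#' @return Invisible list of the four file paths.
#' @export
write_cohort <- function(matrices, out_dir, populations = "POP1",
                         test_loci = character(0), truth = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_haps(matrices[[1]])
  stopifnot(all(vapply(matrices, n_haps, integer(1)) == n))
  n_samp <- n / 2L
  samples <- sprintf("sim_%03d", seq_len(n_samp))
  hap_ids <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  block <- ceiling(seq_len(n_samp) / (n_samp / length(populations)))
  panel <- data.frame(sample = samples,
                      population = populations[pmin(block, length(populations))])
  big <- hap_matrix(do.call(cbind, lapply(matrices, function(m) m$data)),
                    do.call(rbind, c(lapply(matrices, function(m) m$sites),
                                     list(make.row.names = FALSE))),
                    hap_ids, polarized = TRUE)
  vcf <- file.path(out_dir, "cohort.vcf")
  write_phased_vcf(big, vcf)
  panel_path <- file.path(out_dir, "panel.tsv")
  write.table(panel, panel_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.numeric(test_loci)) test_loci <- names(matrices)[test_loci]
  lens <- vapply(matrices, function(m)
    attr(m, "locus_length") %||% (max(m$sites$pos) + 1L), integer(1))
  regs <- region(names(matrices), 0L, lens,
                 ifelse(names(matrices) %in% test_loci, "test", "control"))
  bed <- file.path(out_dir, "loci.bed")
  write_regions_bed(regs, bed)
  tr <- data.frame(locus = names(matrices),
                   role = ifelse(names(matrices) %in% test_loci, "test", "control"),
                   focal_id = vapply(matrices, function(m)
                     attr(m, "focal_id") %||% NA_character_, character(1)))
  if (!is.null(truth)) tr <- cbind(tr, truth)
  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(tr, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(vcf = vcf, panel = panel_path, bed = bed, truth = truth_path))
}
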