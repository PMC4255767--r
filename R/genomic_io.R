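#' Genomic regions
#'
#' Regions are plain data.frames with 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive), the convention of BED. VCF
#' positions are 1-based; conversion happens only at the I/O boundary.
#'
#' @param chrom chromosome / contig name.
#' @param start,end 0-based half-open interval, `start < end`.
#' @param label free-text label (e.g. gene symbol).
#' @return data.frame with columns `chrom, start, end, label`.
#' @export
region <- function(chrom, start, end, label = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0)) stopf("region start must be >= 0")
  if (any(start >= end)) stopf("region requires start < end")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             label = as.character(label), stringsAsFactors = FALSE)
}

#' Extend a region symmetrically
#'
#' Adds `f` bp of flank on each side, clipping at 0. The default scan
#' analyzes genes in 60-kb flanks (30 kb up- and downstream).
#'
#' @param r region data.frame from [region()] / [read_regions_bed()].
#' @param f flank size in bp per side.
#' @export
flank_region <- function(r, f = 30000L) {
  r$start <- pmax(0L, r$start - as.integer(f))
  r$end <- r$end + as.integer(f)
  r
}

#' Read regions from a BED file
#'
#' @param path BED file (0-based half-open); column 4, when present,
#'   becomes the region label.
#' @return region data.frame.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, length(gr))
  region(as.character(GenomicRanges::seqnames(gr)),
         GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), lab)
}

#' Write regions to BED
#'
#' @param r region data.frame.
#' @param path output path.
#' @export
write_regions_bed <- function(r, path) {
  gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1L, r$end))
  if (!all(is.na(r$label))) gr$name <- r$label
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a sample-to-population panel
#'
#' @param path TSV with header `sample<TAB>population`.
#' @return data.frame with character columns `sample`, `population`.
#' @export
read_panel <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(p)))
    stopf("panel must have columns 'sample' and 'population'")
  if (anyDuplicated(p$sample))
    stopf("panel assigns sample '%s' more than once",
          p$sample[duplicated(p$sample)][1])
  p[, c("sample", "population")]
}

#' Read phased genotypes from a VCF into a haplotype matrix
#'
#' Loads a region of a VCF, restricted to the samples of the requested
#' populations, and transcribes phased genotypes into a 0/1 haplotype
#' matrix (two rows per sample). Sites are filtered to biallelic SNVs;
#' any site with a missing or unphased genotype among the selected
#' samples is dropped (counted, not imputed). The `AA` INFO tag, when
#' present, is carried along as the ancestral-allele annotation for
#' [polarize()].
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param region single-row region data.frame, or `NULL` for the whole
#'   file.
#' @param panel panel data.frame ([read_panel()]); every requested sample
#'   must be genotyped in the VCF.
#' @param populations character vector of population labels to load;
#'   `NULL` loads every panel sample.
#' @param verbose emit a message with exclusion counts.
#' @return A `hap_matrix` (unpolarized) with attribute `exclusions`, a
#'   named integer vector of per-reason dropped-site counts.
#' @export
read_phased_vcf <- function(path, region = NULL, panel = NULL,
                            populations = NULL, verbose = TRUE) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stopf("VCF %s has no GT field", path)
  vcf_samples <- colnames(gt)

  samples <- vcf_samples
  if (!is.null(panel)) {
    samples <- panel$sample
    if (!is.null(populations)) {
      unknown_pop <- setdiff(populations, unique(panel$population))
      if (length(unknown_pop))
        stopf("population '%s' not present in panel", unknown_pop[1])
      samples <- panel$sample[panel$population %in% populations]
    }
    missing <- setdiff(samples, vcf_samples)
    if (length(missing))
      stopf("sample '%s' requested by panel but absent from VCF", missing[1])
  }
  gt <- gt[, samples, drop = FALSE]

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  altl <- rr$ALT

  excl <- c(out_of_region = 0L, multiallelic = 0L, indel = 0L,
            missing_or_unphased = 0L, duplicate_position = 0L)

  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    stopifnot(nrow(region) == 1)
    inside <- chrom == region$chrom & pos >= region$start + 1L & pos <= region$end
    excl["out_of_region"] <- sum(!inside)
    keep <- keep & inside
  }
  n_alt <- S4Vectors::elementNROWS(altl)
  bi <- n_alt == 1L
  excl["multiallelic"] <- sum(keep & !bi)
  keep <- keep & bi
  alt <- rep(NA_character_, length(pos))
  alt[bi] <- as.character(unlist(altl[bi]))
  snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  excl["indel"] <- sum(keep & !snv)
  keep <- keep & snv

  ok_gt <- gt %in% c("0|0", "0|1", "1|0", "1|1")
  dim(ok_gt) <- dim(gt)
  complete <- rowSums(ok_gt) == ncol(gt)
  n_inc <- sum(keep & !complete)
  if (n_inc > 0)
    warnf("%d site(s) dropped for missing or unphased genotypes", n_inc)
  excl["missing_or_unphased"] <- n_inc
  keep <- keep & complete

  idx <- which(keep)
  idx <- idx[order(chrom[idx], pos[idx])]
  dup <- duplicated(paste(chrom[idx], pos[idx]))
  excl["duplicate_position"] <- sum(dup)
  idx <- idx[!dup]

  aa <- VariantAnnotation::info(vcf)$AA
  aa <- if (is.null(aa)) rep(NA_character_, length(pos)) else toupper(as.character(aa))
  aa[!aa %in% c("A", "C", "G", "T")] <- NA_character_

  # transcribe GT strings: haplotype 1 is the character before '|'
  g <- gt[idx, , drop = FALSE]
  h1 <- substr(g, 1L, 1L) == "1"
  h2 <- substr(g, 3L, 3L) == "1"
  n_s <- length(samples)
  data <- matrix(0L, nrow = 2L * n_s, ncol = length(idx))
  data[seq(1L, 2L * n_s, by = 2L), ] <- t(h1) + 0L
  data[seq(2L, 2L * n_s, by = 2L), ] <- t(h2) + 0L
  hap_ids <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))

  ids <- rownames(gt)[idx]
  if (is.null(ids)) ids <- paste0(chrom[idx], ":", pos[idx])
  sites <- data.frame(chrom = chrom[idx], pos = pos[idx], id = ids,
                      ref = ref[idx], alt = alt[idx], aa = aa[idx],
                      stringsAsFactors = FALSE)
  if (verbose)
    message(sprintf("read_phased_vcf: %d sites retained; exclusions: %s",
                    length(idx), paste(names(excl), excl, sep = "=", collapse = ", ")))
  hm <- hap_matrix(data, sites, hap_ids, polarized = FALSE)
  attr(hm, "exclusions") <- excl
  hm
}

#' Write a haplotype matrix as a phased VCF
#'
#' Emits a minimal valid VCF 4.2 with phased GT and, when the ancestral
#' allele is known, the `AA` INFO tag. The inverse of [read_phased_vcf()]
#' for data produced by this package.
#'
#' @param x `hap_matrix`; rows must come in sample pairs (`_1`, `_2`).
#' @param path output path (`.vcf`, plain text).
#' @export
write_phased_vcf <- function(x, path) {
  if (n_haps(x) %% 2L != 0L)
    stopf("write_phased_vcf needs an even number of haplotypes (diploid samples)")
  samples <- unique(sub("_[12]$", "", x$hap_ids))
  if (length(samples) * 2L != n_haps(x))
    stopf("hap_ids must pair as <sample>_1/<sample>_2")
  s <- x$sites
  if (x$polarized) {
    # restore ref/alt encoding: column value 1 means derived; the VCF GT
    # must encode the alt allele, so flip columns whose ancestral is alt
    anc <- s$aa
    flip <- !is.na(anc) & anc == s$alt
    d <- x$data
    d[, flip] <- 1L - d[, flip, drop = FALSE]
  } else d <- x$data
  h1 <- d[seq(1L, n_haps(x), by = 2L), , drop = FALSE]
  h2 <- d[seq(2L, n_haps(x), by = 2L), , drop = FALSE]
  gt_cols <- vapply(seq_len(nrow(h1)), function(i)
    paste0(h1[i, ], "|", h2[i, ]), character(ncol(d)))
  if (is.null(dim(gt_cols))) gt_cols <- matrix(gt_cols, nrow = ncol(d))
  info <- ifelse(is.na(s$aa), ".", paste0("AA=", s$aa))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=hapsweep",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0(sprintf("##contig=<ID=%s>", unique(s$chrom)), collapse = "\n"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- cbind(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", info, "GT",
                gt_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Ancestral allele by outgroup parsimony
#'
#' Assigns the ancestral state of a biallelic ingroup site from one or
#' more outgroup observations: the ingroup allele matched by a strict
#' majority of the non-missing outgroup alleles is declared ancestral.
#' Ties, all-missing outgroups, and majority alleles matching neither
#' ingroup allele return `"unresolved"`.
#'
#' @param outgroup character vector of outgroup alleles (`NA` = missing).
#' @param ref,alt the two ingroup alleles.
#' @return `"ref"`, `"alt"` or `"unresolved"`.
#' @examples
#' parsimony_ancestral(c("A", "A", "A"), "A", "G")  # "ref"
#' parsimony_ancestral(c("A", "G", NA), "A", "G")   # "unresolved" (tie)
#' @export
parsimony_ancestral <- function(outgroup, ref, alt) {
  obs <- toupper(outgroup[!is.na(outgroup) & outgroup != "." & outgroup != ""])
  if (length(obs) == 0) return("unresolved")
  tab <- table(obs)
  top <- names(tab)[tab == max(tab)]
  if (length(top) != 1) return("unresolved")
  if (top == toupper(ref)) "ref" else if (top == toupper(alt)) "alt" else "unresolved"
}

#' Polarize a haplotype matrix to ancestral/derived
#'
#' Re-encodes the matrix so that 1 always means the *derived* allele.
#' The ancestral allele per site comes, in order of precedence, from an
#' explicit lookup table, from the VCF `AA` annotation carried in
#' `x$sites$aa`, or from outgroup parsimony. Sites whose ancestral state
#' is unresolved, or equals neither ref nor alt, are removed (DAF-based
#' statistics cannot use them).
#'
#' @param x unpolarized `hap_matrix`.
#' @param table optional data.frame `chrom, pos, ancestral` overriding the
#'   VCF annotation.
#' @param outgroups optional character matrix (sites x outgroups) of
#'   outgroup alleles used, via [parsimony_ancestral()], for sites still
#'   unresolved after table and annotation.
#' @param verbose message the number of dropped sites.
#' @return Polarized `hap_matrix`; `sites$aa` holds the ancestral base.
#' @export
polarize <- function(x, table = NULL, outgroups = NULL, verbose = TRUE) {
  if (x$polarized) return(x)
  s <- x$sites
  anc <- toupper(s$aa %||% rep(NA_character_, nrow(s)))
  if (!is.null(table)) {
    key <- paste(s$chrom, s$pos)
    m <- match(key, paste(table$chrom, table$pos))
    hit <- !is.na(m)
    anc[hit] <- toupper(as.character(table$ancestral[m[hit]]))
  }
  if (!is.null(outgroups)) {
    outgroups <- as.matrix(outgroups)
    todo <- which(is.na(anc))
    for (j in todo) {
      r <- parsimony_ancestral(outgroups[j, ], s$ref[j], s$alt[j])
      anc[j] <- switch(r, ref = s$ref[j], alt = s$alt[j], NA_character_)
    }
  }
  status <- ifelse(is.na(anc), "unresolved",
                   ifelse(anc == s$ref, "ref",
                          ifelse(anc == s$alt, "alt", "mismatch")))
  n_mis <- sum(status == "mismatch")
  if (n_mis > 0)
    warnf("%d site(s) dropped: ancestral allele matches neither ref nor alt", n_mis)
  keep <- status %in% c("ref", "alt")
  d <- x$data[, keep, drop = FALSE]
  flip <- status[keep] == "alt"
  d[, flip] <- 1L - d[, flip, drop = FALSE]
  s2 <- s[keep, , drop = FALSE]
  s2$aa <- anc[keep]
  if (verbose && sum(!keep) > 0)
    message(sprintf("polarize: %d of %d sites dropped (unresolved/mismatched ancestral)",
                    sum(!keep), nrow(s)))
  hap_matrix(d, s2, x$hap_ids, polarized = TRUE)
}
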