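test_that("read_phased_vcf transcribes phased GT and applies filter rules", {
  body <- c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1\t0|0",
    "chr1\t200\trs2\tC\tT\t.\tPASS\tAA=T\tGT\t1|0\t0|0\t0|1",
    "chr1\t250\tindel1\tCA\tC\t.\tPASS\t.\tGT\t0|0\t0|1\t0|0",      # indel
    "chr1\t300\trs3\tG\tA\t.\tPASS\tAA=G\tGT\t0|0\t1|0\t1|1",
    "chr1\t350\tmulti1\tG\tA,T\t.\tPASS\t.\tGT\t0|1\t0|2\t0|0",     # multiallelic
    "chr1\t400\trs4\tT\tC\t.\tPASS\tAA=C\tGT\t0|0\t0|1\t1|1",
    "chr1\t450\tmiss1\tA\tC\t.\tPASS\t.\tGT\t./.\t0|1\t0|0",        # missing
    "chr1\t500\tunph1\tA\tC\t.\tPASS\t.\tGT\t0/1\t0|1\t0|0")        # unphased
  vcf <- write_toy_vcf(body)
  panel <- read_panel(toy_panel())
  hm <- suppressWarnings(suppressMessages(
    read_phased_vcf(vcf, panel = panel, verbose = FALSE)))
  expect_equal(dim(hm$data), c(6L, 4L))
  expect_equal(hm$sites$id, c("rs1", "rs2", "rs3", "rs4"))
  # direct transcription: site rs1, samples (0|1, 1|1, 0|0) -> haps 0,1,1,1,0,0
  expect_equal(unname(hm$data[, 1]), c(0L, 1L, 1L, 1L, 0L, 0L))
  excl <- attr(hm, "exclusions")
  expect_equal(unname(excl["indel"]), 1L)
  expect_equal(unname(excl["multiallelic"]), 1L)
  expect_equal(unname(excl["missing_or_unphased"]), 2L)
  expect_equal(hm$sites$aa, c("A", "T", "G", "C"))

  # region restriction uses 0-based half-open internally
  hm2 <- suppressWarnings(suppressMessages(
    read_phased_vcf(vcf, region = region("chr1", 99, 300), panel = panel,
                    verbose = FALSE)))
  expect_equal(hm2$sites$pos, c(100L, 200L, 300L))

  # unknown sample is a named error
  bad_panel <- read_panel(toy_panel(samples = c("NA1", "NA9", "NA3")))
  expect_error(
    suppressWarnings(read_phased_vcf(vcf, panel = bad_panel, verbose = FALSE)),
    "NA9")
  # unknown population likewise
  expect_error(
    suppressWarnings(read_phased_vcf(vcf, panel = panel,
                                     populations = "KHV", verbose = FALSE)),
    "KHV")
})

test_that("population restriction selects the right haplotypes", {
  body <- c("chr1\t100\trs1\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1\t0|0")
  vcf <- write_toy_vcf(body)
  panel <- read_panel(toy_panel())
  hm <- suppressMessages(read_phased_vcf(vcf, panel = panel,
                                         populations = "CEU", verbose = FALSE))
  expect_equal(n_haps(hm), 2L)
  expect_equal(hm$hap_ids, c("NA3_1", "NA3_2"))
})

test_that("parsimony_ancestral follows the strict-majority rule", {
  expect_equal(parsimony_ancestral(c("A", "A", "A"), "A", "G"), "ref")
  expect_equal(parsimony_ancestral(c("G", "G", "A"), "A", "G"), "alt")
  expect_equal(parsimony_ancestral(c("A", "G", NA), "A", "G"), "unresolved")
  expect_equal(parsimony_ancestral(c("C", "C", "C"), "A", "G"), "unresolved")
  expect_equal(parsimony_ancestral(c(NA, NA), "A", "G"), "unresolved")
  expect_equal(parsimony_ancestral("G", "A", "G"), "alt")
})

test_that("polarize flips alt-ancestral columns, drops unresolved, computes DAF", {
  m <- matrix(c(0, 0, 1, 1,   # anc = ref -> unchanged
                0, 0, 1, 1,   # anc = alt -> flipped
                1, 1, 0, 0,   # unresolved -> dropped
                0, 1, 1, 0,   # mismatch -> dropped with warning
                1, 0, 0, 0),  # anc = ref
              nrow = 4)
  hm <- toy_hm(m, polarized = FALSE)
  hm$sites$aa <- c("A", "G", NA, "T", "A")
  expect_warning(polarize(hm, verbose = FALSE), "neither ref nor alt")
  pol <- suppressWarnings(polarize(hm, verbose = FALSE))
  expect_true(pol$polarized)
  expect_equal(n_sites(pol), 3L)
  expect_equal(unname(pol$data[, 2]), c(1L, 1L, 0L, 0L))   # flipped
  expect_equal(unname(pol$data[, 1]), c(0L, 0L, 1L, 1L))   # unchanged
  # DAF + ancestral frequency = 1 at every retained site
  expect_equal(daf(pol) + colMeans(pol$data == 0), rep(1, 3))

  # explicit table overrides the VCF annotation
  tab <- data.frame(chrom = "chr1", pos = 1000L, ancestral = "G")
  pol2 <- suppressWarnings(polarize(hm, table = tab, verbose = FALSE))
  expect_equal(unname(pol2$data[, 1]), c(1L, 1L, 0L, 0L))
})

test_that("polarization is an involution on the allele encoding", {
  set.seed(42)
  m <- random_hm(6, 10)
  hm <- toy_hm(m, polarized = FALSE)
  anc_alt <- sample(c(TRUE, FALSE), 10, replace = TRUE)
  hm$sites$aa <- ifelse(anc_alt, "G", "A")
  pol <- polarize(hm, verbose = FALSE)
  # flipping the designated columns once more restores the original
  back <- pol$data
  back[, anc_alt] <- 1L - back[, anc_alt, drop = FALSE]
  expect_identical(unname(back), unname(m + 0L))
})

test_that("VCF write/read round trip preserves the matrix and ancestral truth", {
  set.seed(7)
  hm <- simulate_neutral(8, 6, locus_length = 5000, chrom = "chr9", seed = 3)
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(hm, path)
  back <- suppressMessages(read_phased_vcf(path, verbose = FALSE))
  pol <- polarize(back, verbose = FALSE)
  expect_equal(unname(pol$data), unname(hm$data))
  expect_equal(pol$sites$pos, hm$sites$pos)
  expect_equal(pol$sites$aa, hm$sites$aa)
  # second round trip is byte-stable
  path2 <- tempfile(fileext = ".vcf")
  write_phased_vcf(pol, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("regions: construction, flanking, BED round trip", {
  expect_error(region("chr1", 10, 10), "start < end")
  r <- region("chr1", 5000, 8000, "GENE1")
  f <- flank_region(r, 30000)
  expect_equal(f$start, 0L)      # clipped at zero
  expect_equal(f$end, 38000L)
  bed <- tempfile(fileext = ".bed")
  write_regions_bed(rbind(r, region("chr2", 0, 100, "GENE2")), bed)
  back <- read_regions_bed(bed)
  expect_equal(back$start, c(5000L, 0L))
  expect_equal(back$end, c(8000L, 100L))
  expect_equal(back$label, c("GENE1", "GENE2"))
})
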