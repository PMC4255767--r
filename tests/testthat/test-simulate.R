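test_that("simulation is reproducible and loci are independently seeded", {
  a <- simulate_neutral(10, 5, seed = 77)
  b <- simulate_neutral(10, 5, seed = 77)
  expect_identical(a$data, b$data)
  expect_identical(a$sites, b$sites)
  expect_false(identical(simulate_neutral(10, 5, seed = 78)$sites$pos,
                         a$sites$pos))
  co <- simulate_cohort(3, "neutral", n = 10, theta = 5, seed = 5)
  co2 <- simulate_cohort(3, "neutral", n = 10, theta = 5, seed = 5)
  expect_identical(co, co2)
  # locus 2 alone reproduces cohort locus 2 (per-locus RNG streams)
  solo <- simulate_neutral(10, 5, chrom = "locus_2",
                           seed = hapsweep:::child_seed(5, 2))
  expect_identical(solo$data, co$locus_2$data)

  i1 <- simulate_island(6, 4, migration = 1, seed = 9)
  expect_identical(i1$data, simulate_island(6, 4, migration = 1, seed = 9)$data)
  s1 <- simulate_sweep(10, 6, 0.7, 0.1, seed = 9)
  expect_identical(s1$data, simulate_sweep(10, 6, 0.7, 0.1, seed = 9)$data)
})

test_that("generated data satisfy the container invariants", {
  set.seed(51)
  for (i in 1:10) {
    hm <- switch(1 + i %% 3,
                 simulate_neutral(12, 8, seed = 100 + i),
                 simulate_island(6, 8, migration = 2, seed = 100 + i),
                 simulate_sweep(12, 8, 0.6, 0.2, seed = 100 + i))
    expect_true(hm$polarized)
    expect_true(all(diff(hm$sites$pos) > 0))
    expect_true(all(hm$data %in% 0:1))
    cs <- colSums(hm$data)
    expect_true(all(cs >= 0 & cs <= n_haps(hm)))
    expect_true(all(hm$sites$ref != hm$sites$alt))
    expect_true(all(hm$sites$aa == hm$sites$ref | hm$sites$aa == hm$sites$alt))
  }
})

test_that("neutral moments approach coalescent expectations (scaled down)", {
  # full-scale versions of these checks live in the acceptance suite
  set.seed(52)
  pis <- replicate(800, theta_pi(simulate_neutral(2, 1, locus_length = 1000)))
  expect_equal(mean(pis), 1, tolerance = 0.1)  # E[pi] = theta
  Ss <- replicate(400, length(hapsweep:::seg_counts(
    simulate_neutral(10, 5, locus_length = 20000)$data)))
  expect_equal(mean(Ss), 5 * sum(1 / (1:9)), tolerance = 0.08)
})

test_that("neutral spectrum is proportional to 1/i (chi-square, alpha = 0.01)", {
  # sites within a locus share one genealogy, so Pearson's chi-square on
  # pooled site counts is overdispersed; test E[S_i] = theta/i across
  # independent replicate loci with a Wald-type chi-square instead,
  # using the empirical between-replicate variances
  set.seed(53)
  n <- 10; theta <- 5; R <- 2000
  counts <- t(replicate(R, derived_spectrum(
    simulate_neutral(n, theta, locus_length = 20000))))
  expected <- theta / (1:(n - 1))
  se <- apply(counts, 2, sd) / sqrt(R)
  chi2 <- sum(((colMeans(counts) - expected) / se)^2)
  expect_lt(chi2, qchisq(0.99, df = n - 1))
})

test_that("island model needs migration and approaches panmixia at high 4Nm", {
  expect_error(simulate_island(6, 4, migration = 0, seed = 1), "migration")
  set.seed(54)
  fst <- unlist(lapply(1:60, function(i) {
    hm <- simulate_island(10, 5, migration = 100, seed = 400 + i)
    panel <- data.frame(sample = sprintf("s%d", 1:10),
                        population = rep(c("A", "B"), each = 5))
    fst_scan(hm, panel, "A", "B")$fst
  }))
  expect_lt(abs(mean(fst)), 0.02)
})

test_that("sweep plants the focal allele and compresses derived diversity", {
  hm <- simulate_sweep(20, 10, sweep_daf = 0.8, compression = 0.02, seed = 60)
  focal <- attr(hm, "focal")
  expect_equal(unname(daf(hm)[focal]), 0.8)
  expect_identical(which(hm$data[, focal] == 1L), 1:16)
  expect_error(simulate_sweep(20, 10, 0.02, 0.5), ">= 2")
  expect_error(simulate_sweep(20, 10, 0.5, 0), "compression")

  # strong compression lowers i_pi_d relative to the c = 1 genealogy
  set.seed(61)
  ipd <- function(cc, i) {
    hm <- simulate_sweep(20, 30, 0.5, cc, locus_length = 50000, seed = 700 + i)
    d <- hm$data[hm$data[, attr(hm, "focal")] == 1, -attr(hm, "focal"), drop = FALSE]
    pairwise_pi_oracle(d)
  }
  lo <- mean(vapply(1:40, function(i) ipd(0.02, i), numeric(1)))
  hi <- mean(vapply(1:40, function(i) ipd(1, i), numeric(1)))
  expect_lt(lo, hi / 2)
})

test_that("write_cohort emits consistent VCF, panel, BED and truth files", {
  td <- tempfile()
  mats <- simulate_cohort(3, "neutral", n = 8, theta = 6, seed = 71,
                          locus_length = 5000)
  paths <- write_cohort(mats, td, populations = c("P1", "P2"),
                        test_loci = "locus_3")
  panel <- read_panel(paths$panel)
  expect_equal(sort(unique(panel$population)), c("P1", "P2"))
  regs <- read_regions_bed(paths$bed)
  expect_equal(regs$label, c("control", "control", "test"))
  expect_equal(regs$end, rep(5000L, 3))
  truth <- read.delim(paths$truth)
  expect_equal(truth$role, c("control", "control", "test"))
  # AA tag in the VCF matches the generator truth at every site
  hm <- suppressMessages(read_phased_vcf(paths$vcf, panel = panel, verbose = FALSE))
  expect_equal(hm$sites$aa, do.call(rbind, lapply(mats, `[[`, "sites"))$aa)
  pol <- polarize(hm, verbose = FALSE)
  expect_equal(unname(pol$data),
               unname(do.call(cbind, lapply(mats, `[[`, "data"))))
})
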