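# DIND fixtures use flank = 2 (4 flanking variants) so every quantity can
# be checked by hand or against the pairwise oracle.

# 6 haplotypes; focal site in the middle; 2 polymorphic flankers per side
dind_fixture <- function() {
  #           f1 f2 FO f3 f4
  m <- rbind(c(1, 0, 1, 0, 0),   # derived carriers: rows 1-3
             c(0, 1, 1, 0, 0),
             c(0, 0, 1, 1, 0),
             c(1, 1, 0, 0, 1),   # ancestral carriers: rows 4-6
             c(0, 0, 0, 1, 1),
             c(1, 0, 0, 0, 0))
  toy_hm(m)
}

# oracle: mean pairwise differences among `rows` over `cols`
class_pi_oracle <- function(m, rows, cols) {
  if (length(rows) < 2) return(0)
  pairwise_pi_oracle(m[rows, cols, drop = FALSE])
}

test_that("dind_statistic equals the pairwise oracle on both allelic classes", {
  hm <- dind_fixture()
  res <- dind_statistic(hm, focal = 3, flank = 2)
  m <- hm$data
  expect_equal(res$i_pi_a, class_pi_oracle(m, 4:6, c(1, 2, 4, 5)))
  expect_equal(res$i_pi_d, class_pi_oracle(m, 1:3, c(1, 2, 4, 5)))
  expect_equal(res$dind, res$i_pi_a / res$i_pi_d)
  expect_false(res$sentinel)

  # ratio arithmetic and the identity case
  expect_equal(dind_statistic(hm, 3, flank = 2)$dind,
               res$i_pi_a / res$i_pi_d)
  # swapping ancestral/derived at the focal site inverts the ratio
  flip <- hm
  flip$data[, 3] <- 1L - flip$data[, 3]
  res2 <- dind_statistic(flip, 3, flank = 2)
  expect_equal(res2$dind, 1 / res$dind, tolerance = 1e-12)
})

test_that("dind is invariant to haplotype order and fires the sentinel at i_pi_d = 0", {
  hm <- dind_fixture()
  perm <- hap_subset(hm, haps = c(4, 1, 6, 2, 5, 3))
  expect_equal(dind_statistic(perm, 3, flank = 2)$dind,
               dind_statistic(hm, 3, flank = 2)$dind)

  # identical derived carriers across the flankers -> sentinel pending
  m <- hm$data
  m[1:3, c(1, 2, 4, 5)] <- 0L
  hs <- toy_hm(m)
  res <- dind_statistic(hs, 3, flank = 2)
  expect_true(res$sentinel)
  expect_equal(res$i_pi_d, 0)
  expect_true(is.na(res$dind))

  # a derived class with a single carrier has no pairs: i_pi_d = 0 -> sentinel
  m2 <- hm$data
  m2[, 3] <- c(1L, 0L, 0L, 0L, 0L, 0L)
  expect_true(dind_statistic(toy_hm(m2), 3, flank = 2)$sentinel)

  expect_error(dind_statistic(hm, 1, flank = 2), "flanking")
  mono <- hm$data; mono[, 3] <- 1L
  expect_error(dind_statistic(toy_hm(mono), 3, flank = 2), "monomorphic")
})

test_that("resolve_sentinels applies max-plus-20 over the whole batch", {
  rec <- data.frame(dind = c(2, 7.3, NA, NA), sentinel = c(FALSE, FALSE, TRUE, TRUE))
  out <- resolve_sentinels(rec)
  expect_equal(out$dind[3:4], c(27.3, 27.3))
  # no sentinels: unchanged
  expect_identical(resolve_sentinels(rec[1:2, ]), rec[1:2, ])
  # two different batches acquire different sentinel values
  recB <- data.frame(dind = c(11, NA), sentinel = c(FALSE, TRUE))
  expect_equal(resolve_sentinels(recB)$dind[2], 31)
  # all-sentinel batch has no finite maximum
  expect_error(resolve_sentinels(data.frame(dind = NA_real_, sentinel = TRUE)),
               "finite maximum")
})

test_that("daf_bin uses right-closed 100 classes", {
  expect_equal(daf_bin(0.005), 0L)
  expect_equal(daf_bin(0.98), 97L)
  expect_equal(daf_bin(0.50), 49L)
  expect_equal(daf_bin(0.01), 0L)     # right endpoint of the first class
  expect_equal(daf_bin(0.0100001), 1L)
  expect_equal(daf_bin(29 / 100), 28L)  # float-representation guard
  expect_error(daf_bin(0), "strictly")
  expect_error(daf_bin(1), "strictly")
})

test_that("uncalibrated_bins flags sentinel-saturated and sparse classes", {
  vals <- c(runif(100, 1, 3), rep(60, 60),          # bin 0: 37.5% sentinels
            runif(200, 1, 3),                        # bin 1: clean
            runif(95, 1, 3), rep(60, 5),             # bin 2: exactly 5%
            runif(10, 1, 3))                         # bin 3: sparse
  bins <- rep(c(0L, 1L, 2L, 3L), c(160, 200, 100, 10))
  sent <- c(rep(c(FALSE, TRUE), c(100, 60)), rep(FALSE, 200),
            rep(c(FALSE, TRUE), c(95, 5)), rep(FALSE, 10))
  null <- build_null(vals, bins = bins, n_classes = 100L, statistic = "dind",
                     sentinel = sent, min_bin_count = 20)
  bad <- uncalibrated_bins(null)
  expect_true(all(c(0L, 2L, 3L) %in% bad))   # 5% boundary is inclusive
  expect_false(1L %in% bad)
  expect_true(all(4:99 %in% bad))            # empty classes are unusable
})

test_that("dind_records + dind_scan wire records through the null", {
  set.seed(21)
  hm <- simulate_neutral(20, 30, locus_length = 50000, seed = 23)
  rec <- dind_records(hm, flank = 5, population = "P")
  eligible <- is.na(rec$skip_reason)
  expect_true(any(eligible))
  expect_true(all(rec$i_pi_a[eligible] >= 0 & rec$i_pi_d[eligible] >= 0))
  expect_true(all(rec$sentinel[eligible] == (rec$i_pi_d[eligible] == 0)))
  # edge sites report the skip reason
  expect_equal(rec$skip_reason[1], "insufficient_flanking_variants")
  rec <- resolve_sentinels(rec)
  keep <- !is.na(rec$dind)
  null <- build_null(rec$dind[keep], bins = rec$daf_bin[keep], n_classes = 100L,
                     sentinel = rec$sentinel[keep], min_bin_count = 2)
  ranked <- dind_scan(rec, null)
  rk <- ranked$rank[!is.na(ranked$rank)]
  expect_true(all(rk >= 0 & rk <= 1))
  # ranks of a null's own members stay below (N-1)/N
  for (b in unique(rec$daf_bin[keep])) {
    arr <- null$bins[[b + 1]]
    if (length(arr) >= 2 && !(b %in% uncalibrated_bins(null)))
      expect_true(all(null_rank(null, arr, b) <= (length(arr) - 1) / length(arr)))
  }
  # a value above every control in a calibrated bin ranks 1
  cal <- setdiff(unique(rec$daf_bin[keep]), uncalibrated_bins(null))
  if (length(cal))
    expect_equal(null_rank(null, 1e6, cal[1]), 1)
})
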