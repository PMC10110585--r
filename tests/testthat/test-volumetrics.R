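test_that("software volume triplet yields contralateral/ipsilateral volumes", {
  expect_equal(pva_parenchymal_volumes(210, 229, 39),
               c(contra = 210, ipsi = 190))
  expect_equal(pva_parenchymal_volumes(100, 150, 50),
               c(contra = 100, ipsi = 100))
  # kidney fully replaced by tumor
  expect_equal(pva_parenchymal_volumes(80, 60, 60)[["ipsi"]], 0)
  expect_error(pva_parenchymal_volumes(100, 50, 60), "exceeds")
  expect_error(pva_parenchymal_volumes(-1, 50, 10), "non-negative")
})

test_that("ellipsoid volume reproduces the worked example and is bilinear", {
  expect_equal(round(lwh_volume(11.0, 4.2, 4.2, 4.1, 4.1), 1), 98.5)
  expect_equal(lwh_volume(11.0, 4.2, 4.2, 4.1, 4.1), 0.52 * 11 * 4.2 * 4.1)
  expect_equal(round(lwh_volume(11.3, 4.8, 4.8, 3.6, 3.6), 1), 101.5)
  # doubling the length exactly doubles the volume
  expect_equal(lwh_volume(22, 4.2, 4.2, 4.1, 4.1),
               2 * lwh_volume(11, 4.2, 4.2, 4.1, 4.1))
  # swapping the paired measurements changes nothing
  expect_equal(lwh_volume(12, 3.9, 4.4, 3.8, 4.2),
               lwh_volume(12, 4.4, 3.9, 4.2, 3.8))
  expect_error(lwh_volume(11, 0, 4, 4, 4), "positive")
  expect_warning(lwh_volume(3, 4.2, 4.2, 4.1, 4.1), "implausible")
})

test_that("volume-share SRF is a normalised, scale-invariant fraction", {
  expect_equal(srf_from_volumes(210, 190)$srf_contralateral, 0.525)
  expect_equal(srf_from_volumes(7, 7)$srf_contralateral, 0.5)
  expect_equal(srf_from_volumes(98.4984, 101.5373)$srf_contralateral,
               0.4924, tolerance = 1e-4)
  set.seed(4)
  for (i in 1:25) {
    a <- runif(1, 1, 400); b <- runif(1, 1, 400); c <- runif(1, 0.01, 50)
    expect_equal(srf_from_volumes(c * a, c * b)$srf_contralateral,
                 srf_from_volumes(a, b)$srf_contralateral, tolerance = 1e-12)
  }
  # round trip: triplet -> volumes -> SRF equals direct subtraction
  v <- pva_parenchymal_volumes(170, 200, 46)
  expect_equal(srf_from_volumes(v[["contra"]], v[["ipsi"]])$srf_contralateral,
               170 / (170 + 154))
})

test_that("displayed percent pair rounds half away from zero and sums to 100", {
  expect_equal(srf_percent_display(0.525),
               c(contralateral = 53L, ipsilateral = 47L))
  expect_equal(srf_percent_display(0.4924),
               c(contralateral = 49L, ipsilateral = 51L))
  expect_equal(srf_percent_display(0.5),
               c(contralateral = 50L, ipsilateral = 50L))
  set.seed(9)
  for (s in runif(100)) {
    expect_equal(sum(srf_percent_display(s)), 100L)
  }
  expect_error(srf_percent_display(1.2), "fraction")
})

test_that("rater concordance summarises absolute SRF discrepancy", {
  a <- data.frame(contra_length = 11, contra_ap1 = 4.2, contra_ap2 = 4.2,
                  contra_ml1 = 4.1, contra_ml2 = 4.1,
                  ipsi_length = 11.3, ipsi_ap1 = 4.8, ipsi_ap2 = 4.8,
                  ipsi_ml1 = 3.6, ipsi_ml2 = 3.6)
  expect_equal(compare_raters(a, a)$mean, 0)
  b <- a
  b$contra_length <- 11.6 # one rater measures a slightly longer kidney
  out <- compare_raters(a, b)
  expect_gt(out$mean, 0)
  expect_lt(out$mean, 5)
  expect_equal(out$mean, out$discrepancy_pct[1])
})
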