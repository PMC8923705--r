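test_that("psnr hand values", {
  a <- flat_volume(0, n = 8); b <- flat_volume(255, n = 8)
  expect_equal(psnr(a, a), Inf)
  expect_equal(psnr(a, b, 255), 0)
  c1 <- flat_volume(100, n = 8); c2 <- flat_volume(125.5, n = 8)
  expect_equal(psnr(c1, c2, 255), 20)
  expect_error(psnr(a, flat_volume(0, n = 9)), "same grid")
})

test_that("psnr decreases monotonically with added noise", {
  set.seed(21)
  ref <- gridded_volume(array(runif(12^3, 0, 255), c(12, 12, 12)), 1)
  ps <- sapply(c(1, 5, 20, 60), function(s) {
    x <- with_data(ref, ref$data + array(rnorm(12^3, sd = s), dim(ref$data)))
    psnr(x, ref, 255)
  })
  expect_true(all(diff(ps) < 0))
})

test_that("ssim closed form for constant volumes and affine degradation", {
  a <- flat_volume(0, n = 16); b <- flat_volume(255, n = 16)
  expect_equal(ssim(a, a), 1)
  # zero variances: SSIM = C1 / (255^2 + C1)
  expect_equal(ssim(a, b, 255), 6.5025 / (255^2 + 6.5025), tolerance = 1e-9)
  set.seed(22)
  ref <- gridded_volume(array(runif(16^3, 0, 100), c(16, 16, 16)), 1)
  gain2 <- with_data(ref, 2 * ref$data)
  zero <- with_data(ref, 0 * ref$data)
  expect_lt(ssim(gain2, ref), 1)
  expect_gt(ssim(gain2, ref), ssim(zero, ref))
})

test_that("detectability index counts overlap with truth vessels", {
  d <- c(5, 5, 4)
  truth <- gridded_volume(array(0, d), 1)
  truth$data[1:60] <- 1                     # 60 artery voxels
  truth$data[61:100] <- 2                   # 40 vein voxels
  det_all <- gridded_volume(array(as.numeric(truth$data > 0), d), 1)
  expect_equal(detection_metrics(det_all, truth), 100)
  det_none <- gridded_volume(array(0, d), 1)
  expect_equal(detection_metrics(det_none, truth), 0)
  det_half <- gridded_volume(array(0, d), 1)
  det_half$data[1:50] <- 1                  # 50 of 100 vessel voxels
  expect_equal(detection_metrics(det_half, truth), 50)
  expect_error(detection_metrics(det_all, gridded_volume(array(0, d), 1)),
               "no vessel")
})

test_that("classification metrics follow the count formulas in both modes", {
  d <- c(10, 10, 2)
  truth <- gridded_volume(array(0, d), 1)
  truth$data[1:60] <- 1; truth$data[61:100] <- 2
  pred <- truth
  m <- classification_metrics(pred, truth, "known_structure")
  expect_equal(m$tar, 100); expect_equal(m$tvr, 100); expect_equal(m$acc, 100)

  pred2 <- truth
  pred2$data[1:30] <- 2                     # 30 arteries misclassified
  m2 <- classification_metrics(pred2, truth, "known_structure")
  expect_equal(m2$tar, 50)
  expect_equal(m2$acc, (30 + 40) / 100 * 100)
  # ACC is the vessel-count-weighted mean of TAR and TVR
  expect_equal(m2$acc, (m2$tar * 60 + m2$tvr * 40) / 100)

  det <- gridded_volume(array(0, d), 1)
  det$data[1:80] <- 1                       # last 20 vein voxels undetected
  m3 <- classification_metrics(pred, truth, "detected_structure",
                               detected = det)
  expect_equal(m3$dtar, 100)
  expect_equal(m3$dtvr, 100 * 20 / 40)
  expect_equal(m3$dacc, 100 * (60 + 20) / 100)
  # detected-and-correct voxels are detected: DACC <= DET
  expect_lte(m3$dacc, detection_metrics(det, truth))
})

test_that("depth-binned metrics assign vessels to half-open 10 mm bins", {
  d <- c(6, 6, 3)
  truth <- gridded_volume(array(0, d), 1)
  truth$data[1:40] <- 1; truth$data[41:60] <- 2
  depth <- gridded_volume(array(NA_real_, d), 1, allow_na = TRUE)
  depth$data[1:20] <- 5       # bin [0,10)
  depth$data[21:40] <- 15     # bin [10,20)
  depth$data[41:60] <- 10     # exactly 10 -> bin [10,20)
  det <- gridded_volume(array(0, d), 1); det$data[1:50] <- 1
  pred <- truth; pred$data[21:30] <- 2
  tab <- depth_binned_metrics(pred, truth, det, depth)
  expect_equal(tab$n_vessel, c(20L, 40L, 0L, 0L, 0L))
  expect_equal(tab$det[1], 100)
  expect_equal(tab$det[2], 100 * 30 / 40)
  expect_equal(tab$acc[1], 100)
  expect_equal(tab$acc[2], 100 * 30 / 40)
  expect_true(all(is.na(tab$det[3:5])))
})

test_that("reference improvement ratios reproduce the published averages", {
  r <- average_improvement_ratios()
  expect_equal(round(r$det_vs_none, 2), 6.66)
  expect_equal(round(r$det_vs_clahe, 2), 2.37)
  expect_equal(round(r$dacc_vs_none, 2), 5.81)
  expect_equal(round(r$dacc_vs_clahe, 2), 2.34)
})
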