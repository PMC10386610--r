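tf <- table2_fixture()

test_that("per-sample MAE matches hand-checked worked-example cells", {
  # S5: GT (9.5, 12.1, 10.7, 1.8) vs Pre (9.2, 12, 10.9, 1.8)
  expect_equal(mae(tf$gt[5, ], tf$pred[5, ]), 0.15)
  expect_equal(mae(c(FL = 1, FW = 1, VL = 1, VW = 1),
                   c(FL = 2, FW = 0, VL = 2, VW = 0)), 1)
  expect_equal(mae(tf$gt[1, ], tf$gt[1, ]), 0)
  expect_error(mae(c(FL = 1, FW = 2), c(FL = 1, FW = 2)), "missing")
})

test_that("per-sample MAPE matches hand-checked worked-example cells", {
  expect_equal(round(mape(tf$gt[3, ], tf$pred[3, ]), 2), 2.75)
  expect_equal(mape(c(FL = 10, FW = 10, VL = 10, VW = 10),
                    c(FL = 11, FW = 9, VL = 11, VW = 9)), 10)
  expect_equal(mape(tf$gt[2, ], tf$gt[2, ]), 0)
  zero <- c(FL = 0, FW = 1, VL = 1, VW = 1)
  expect_error(mape(zero, zero + 0.1), "FL")
})

test_that("error metrics have the expected invariances", {
  set.seed(7)
  gt <- c(FL = 12, FW = 9, VL = 14, VW = 1.5)
  pr <- gt + runif(4, -1, 1)
  perm <- c("VW", "FL", "VL", "FW")
  expect_equal(mae(gt[perm], pr[perm]), mae(gt, pr))
  expect_equal(mape(gt[perm], pr[perm]), mape(gt, pr))
  expect_equal(mae(gt + 5, pr + 5), mae(gt, pr))          # translation
  expect_equal(mape(3 * gt, 3 * pr), mape(gt, pr))        # scale
})

test_that("table evaluation reproduces the consistent printed cells", {
  ev <- evaluate_table(tf$gt, tf$pred)
  per <- ev$per_sample
  # printed MAE cells that agree with the definition at 2 decimals
  for (s in c(2, 5, 7, 9))
    expect_equal(round(per$mae[s], 2), tf$printed$mae[s])
  # printed MAPE cells that agree at 2 decimals
  for (s in c(3, 5, 9))
    expect_equal(round(per$mape_pct[s], 2), tf$printed$mape_pct[s])
  expect_true(all(per$fpc_match))
  expect_equal(ev$summary$fpc_match_rate, 1)
  expect_equal(ev$summary$n_samples, 10)
})

test_that("some printed worked-example cells contradict the definitions", {
  ev <- evaluate_table(tf$gt, tf$pred)
  per <- ev$per_sample
  # recomputation disagrees with these printed cells: documented, not
  # reproduced
  expect_equal(round(per$mae[4], 4), 0.1275)       # printed as 0.15
  expect_false(round(per$mae[4], 2) == tf$printed$mae[4])
  expect_gt(per$mape_pct[8], 5)                    # printed as 1.9
  expect_false(round(per$mape_pct[4], 2) == tf$printed$mape_pct[4])
})

test_that("table evaluation handles trivial and malformed inputs", {
  sub <- tf$gt[1:3, ]
  ev <- evaluate_table(sub, sub)
  expect_true(all(ev$per_sample$mae == 0))
  expect_true(all(ev$per_sample$mape_pct == 0))
  expect_equal(ev$summary$fpc_match_rate, 1)

  one <- evaluate_table(tf$gt[4, ], tf$pred[4, ])
  expect_equal(one$summary$mean_mae, one$per_sample$mae)

  expect_error(evaluate_table(tf$gt, tf$pred[1:9, ]), "S10")
  expect_error(evaluate_table(tf$gt[, -2], tf$pred), "missing columns")
})

test_that("property tables round-trip through CSV", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_property_table(tf$gt, p)
  back <- read_property_table(p)
  expect_equal(back, tf$gt)
  # the measurement schema with _mm suffixes is accepted too
  meas <- tf$pred
  names(meas) <- c("sample_id", "FL_mm", "FW_mm", "VL_mm", "VW_mm", "FPC")
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(meas, p2, row.names = FALSE)
  expect_equal(read_property_table(p2)$FL, tf$pred$FL)
})

test_that("mask AP equals brute-force enumeration on small cases", {
  gts <- list(list(mask = tiny_mask(1:4), category = "a"),
              list(mask = tiny_mask(5:8), category = "a"))
  # one true match at the top score, then a false positive
  preds <- list(list(mask = tiny_mask(1:4), score = 0.9, category = "a"),
                list(mask = tiny_mask(33:36), score = 0.8, category = "a"))
  res <- mask_average_precision(preds, gts)
  expect_equal(res$mAP, 0.5)
  expect_equal(res$mAP, oracle_ap(preds, gts))

  # perfect detector: AP 1 per class regardless of scores
  gts2 <- list(list(mask = tiny_mask(1:4), category = "a"),
               list(mask = tiny_mask(9:12), category = "b"))
  preds2 <- list(list(mask = tiny_mask(1:4), score = 0.2, category = "a"),
                 list(mask = tiny_mask(9:12), score = 0.7, category = "b"))
  res2 <- mask_average_precision(preds2, gts2)
  expect_equal(unname(res2$per_class), c(1, 1))
  expect_equal(res2$mAP, 1)

  # no predictions at all
  expect_equal(mask_average_precision(list(), gts)$mAP, 0)
})

test_that("AP matches the exhaustive oracle on seeded random cases", {
  set.seed(11)
  for (i in 1:8) {
    n_gt <- sample(1:3, 1)
    n_pred <- sample(0:5, 1)
    gts <- lapply(seq_len(n_gt), function(j)
      list(mask = tiny_mask(sample(64, 6)), category = "c"))
    preds <- lapply(seq_len(n_pred), function(j) {
      src <- if (runif(1) < 0.5 && n_gt > 0)
        which(gts[[sample(n_gt, 1)]]$mask) else sample(64, 6)
      list(mask = tiny_mask(src), score = runif(1), category = "c")
    })
    got <- if (n_pred == 0) 0 else
      mask_average_precision(preds, gts)$per_class[["c"]]
    expect_equal(got, oracle_ap(preds, gts), tolerance = 1e-12)
  }
})

test_that("AP respects its ordering properties", {
  gts <- list(list(mask = tiny_mask(1:4), category = "a"),
              list(mask = tiny_mask(5:8), category = "a"))
  preds <- list(list(mask = tiny_mask(1:4), score = 0.9, category = "a"),
                list(mask = tiny_mask(5:8), score = 0.6, category = "a"))
  base <- mask_average_precision(preds, gts)$mAP
  expect_true(base >= 0 && base <= 1)
  # adding a lowest-score false positive never increases AP
  worse <- c(preds, list(list(mask = tiny_mask(40:43), score = 0.1,
                              category = "a")))
  expect_lte(mask_average_precision(worse, gts)$mAP, base)
  # dropping an unmatched GT instance never decreases AP
  gts3 <- c(gts, list(list(mask = tiny_mask(50:53), category = "a")))
  expect_gte(base, mask_average_precision(preds, gts3)$mAP)

  # classes absent from GT are excluded from the mean
  preds_b <- c(preds, list(list(mask = tiny_mask(20:23), score = 0.5,
                                category = "zz")))
  res <- mask_average_precision(preds_b, gts)
  expect_named(res$per_class, "a")
})
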