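test_that("blank filter keeps >10-fold features, drops exact 10-fold, keeps blank-absent", {
  m <- rbind(c(1000, 1000, 50),   # ratio 20 -> kept
             c(500, 500, 50),     # ratio exactly 10 -> removed
             c(500, 500, 0))      # blank mean 0 -> kept
  ft <- make_ft(m, roles = c("sample", "sample", "blank"),
                groups = c("case", "control", ""))
  out <- quiet(blank_filter(ft))
  expect_equal(out$features$feature_id, c("F001", "F003"))
  # surviving intensities untouched; idempotent
  expect_identical(out$intensities, ft$intensities[c(1, 3), ])
  expect_identical(quiet(blank_filter(out))$intensities, out$intensities)
  # no blanks -> instructive error
  ft2 <- make_ft(m[, 1:2], roles = c("sample", "sample"),
                 groups = c("case", "control"))
  expect_error(blank_filter(ft2), "skip")
})

test_that("QC CV filter uses the n-1 sd and an inclusive 30% threshold", {
  m <- rbind(c(90, 100, 110),    # CV = 10% (sd 10, mean 100) -> kept
             c(100, 100, 100),   # CV = 0 -> kept
             c(70, 100, 130),    # CV = 30% exactly -> excluded
             c(0, 0, 0))         # QC mean 0 -> excluded
  expect_equal(100 * sd(m[3, ]) / mean(m[3, ]), 30)
  ft <- make_ft(m, roles = rep("qc", 3))
  out <- quiet(qc_cv_filter(ft))
  expect_equal(out$features$feature_id, c("F001", "F002"))
  expect_identical(quiet(qc_cv_filter(out))$intensities, out$intensities)
  expect_error(qc_cv_filter(make_ft(m[, 1:2], roles = rep("qc", 2))),
               "at least 3")
})

test_that("drift correction is exact on noise-free linear drift and inert on flat QCs", {
  # schedule: QC s s QC s s QC s s QC s s QC  (6 QCs incl. ends)
  roles <- c("qc", "sample", "sample", "qc", "sample", "sample", "qc",
             "sample", "sample", "qc", "sample", "sample", "qc", "qc")
  groups <- ifelse(roles == "sample",
                   rep(c("case", "control"), 5)[seq_len(sum(roles == "sample"))], "")
  groups[roles != "sample"] <- ""
  n <- length(roles)
  drift <- seq(1, 2, length.out = n)           # 2-fold linear drift
  m <- rbind(1000 * drift, 500 * drift)
  ft <- make_ft(m, roles = roles, groups = groups)

  pre <- cv_profile(ft, "qc")$cv_values
  out <- quiet(lowess_drift_correct(ft, span = 0.5))
  post <- cv_profile(out, "qc")$cv_values
  expect_equal(out$state, "drift_corrected")
  expect_true(all(post < 0.05 * pre))          # >95% CV reduction, noise-free

  # constant QCs: flat fit, everything unchanged
  flat <- make_ft(rbind(rep(1000, n), rep(2, n)), roles = roles, groups = groups)
  out2 <- quiet(lowess_drift_correct(flat))
  expect_equal(out2$intensities, flat$intensities, tolerance = 1e-12)
  expect_error(lowess_drift_correct(out2), "raw")  # forward-only state
})

test_that("a single outlier QC does not inflate QC CV after robust correction", {
  roles <- c(rep(c("qc", "sample", "sample"), 4), "qc")
  groups <- ifelse(roles == "sample", rep(c("case", "control"), 4), "")
  n <- length(roles)
  base <- rep(1000, n)
  qc_idx <- which(roles == "qc")
  base[qc_idx[3]] <- 3000                       # one wild QC
  ft <- make_ft(matrix(base, 1), roles = roles, groups = groups)
  pre <- cv_profile(ft, "qc")$cv_values
  post <- cv_profile(quiet(lowess_drift_correct(ft)), "qc")$cv_values
  expect_lte(post, pre + 1e-9)
})

test_that("protein normalization scales sample columns only and is homogeneous", {
  ft <- make_ft(matrix(c(5000, 5000, 5000), 1),
                roles = c("sample", "sample", "qc"),
                groups = c("case", "control", ""),
                protein = c(10, 1, NA))
  out <- protein_normalize(ft)
  expect_equal(unname(out$intensities[1, ]), c(500, 5000, 5000))
  expect_equal(out$state, "protein_normalized")
  # doubling all protein amounts halves all sample amounts
  ft2 <- ft
  ft2$meta$protein_ug <- ft$meta$protein_ug * 2
  out2 <- protein_normalize(ft2)
  sa <- ft2$meta$role == "sample"
  expect_equal(out2$intensities[, sa], out$intensities[, sa] / 2)
  # missing protein -> error
  ft3 <- ft
  ft3$meta$protein_ug[1] <- NA
  expect_error(protein_normalize(ft3), "protein_ug")
})

test_that("TIC normalization equalizes column sums and fixes a scaled column", {
  m <- cbind(c(10, 20, 30), c(10, 20, 30), c(20, 40, 60))
  ft <- make_ft(m, roles = c("sample", "sample", "sample"),
                groups = c("case", "control", "control"))
  out <- tic_normalize(ft)
  cs <- colSums(out$intensities)
  expect_equal(max(cs) - min(cs), 0, tolerance = 1e-9)
  expect_equal(out$intensities[, 3], out$intensities[, 1])
  # homogeneity of degree 1
  ft2 <- ft; ft2$intensities <- ft$intensities * 3
  expect_equal(tic_normalize(ft2)$intensities, out$intensities * 3)
  ftz <- make_ft(cbind(c(1, 1), c(0, 0)), roles = c("sample", "sample"),
                 groups = c("case", "control"))
  expect_error(tic_normalize(ftz), "inj02")
})

test_that("isomer summation merges identical sum compositions, keeping the top member", {
  m <- rbind(c(100, 100), c(250, 260), c(40, 40))
  ft <- make_ft(m, roles = c("sample", "sample"),
                groups = c("case", "control"),
                names = c("PC 34:2", "PC 16:0_18:2", "PC O-34:2"))
  out <- quiet(sum_isomers(ft))
  expect_equal(nrow(out$features), 2L)          # ether species kept apart
  i <- which(out$features$lipid_class == "PC" &
               out$features$ether_linkage == "none")
  expect_equal(unname(out$intensities[i, ]), c(350, 360))
  expect_equal(out$features$feature_id[i], "F002")  # most intense member
  # no duplicates -> identity
  expect_identical(quiet(sum_isomers(out))$intensities, out$intensities)
  # three duplicates -> n decreases by 2
  ft3 <- make_ft(matrix(1, 3, 2), roles = c("sample", "sample"),
                 groups = c("case", "control"),
                 names = rep("TG 52:3", 3))
  expect_equal(nrow(quiet(sum_isomers(ft3))$features), 1L)
})

test_that("implausible lipids are excluded; unannotated rows untouched", {
  ft <- make_ft(matrix(1, 4, 2), roles = c("sample", "sample"),
                groups = c("case", "control"),
                names = c("TG 54:13", "PC 35:2", "PC 34:2", "junk name"))
  out <- quiet(exclude_implausible(ft))
  expect_equal(out$features$name, c("PC 34:2", "junk name"))
  expect_identical(quiet(exclude_implausible(out))$features, out$features)
  # configurable: keep odd chains
  out2 <- quiet(exclude_implausible(ft, drop_odd = FALSE))
  expect_true("PC 35:2" %in% out2$features$name)
})

test_that("class totals sum member amounts and compare groups", {
  tg <- two_group_roles(3)
  m <- rbind(c(100, 110, 90, 100, 110, 90),
             c(200, 210, 190, 200, 210, 190),
             c(50, 55, 45, 50, 55, 45))
  ft <- make_ft(m, roles = tg$roles, groups = tg$groups,
                names = c("Cer 34:1", "Cer 36:1", "PC 34:2"),
                state = "protein_normalized")
  cs <- class_totals(ft)
  cer <- cs[cs$lipid_class == "Cer", ]
  expect_equal(cer$n_features, 2L)
  expect_equal(cer$amount_case, mean(c(300, 320, 280)))  # Eq-style row sums
  # identical groups: FC 1, p > 0.99
  expect_equal(cer$class_fold_change, 1)
  expect_gt(cer$t_p_value, 0.99)

  # additivity: splitting a feature row leaves class amounts unchanged
  m2 <- rbind(m[1, ] * 0.3, m[1, ] * 0.7, m[2, ], m[3, ])
  ft2 <- make_ft(m2, roles = tg$roles, groups = tg$groups,
                 names = c("Cer 34:1", "Cer 40:1", "Cer 36:1", "PC 34:2"),
                 state = "protein_normalized")
  cs2 <- class_totals(ft2)
  expect_equal(cs2[cs2$lipid_class == "Cer", "amount_case"], cer$amount_case)
  expect_error(class_totals(make_ft(m, roles = tg$roles, groups = tg$groups)),
               "normalized")
})

test_that("class totals recover a 3-fold ceramide spike within sampling error", {
  b <- generate_batch(sim_config(seed = 21, noise_cv = 0.15,
                                 spikes = data.frame(selector = "Cer",
                                                     fold_change = 3),
                                 unannotated_fraction = 0))
  ft <- protein_normalize(b$ft)
  cs <- class_totals(ft)
  fc <- cs$class_fold_change[cs$lipid_class == "Cer"]
  expect_gt(fc, 2.5)
  expect_lt(fc, 3.5)
})

test_that("cv_profile computes acceptability and flags absent strata", {
  ft <- make_ft(matrix(5, 4, 3), roles = rep("qc", 3))
  prof <- cv_profile(ft, "qc")
  expect_equal(prof$pct_acceptable, 100)
  expect_error(cv_profile(ft, "sample"), "at least 3")

  # simulated QC noise sigma/mu = 0.1 -> median CV ~ 10%
  b <- generate_batch(sim_config(seed = 8, n_per_group = 10, noise_cv = 0.1))
  med <- median(cv_profile(b$ft, "qc")$cv_values, na.rm = TRUE)
  expect_gt(med, 7); expect_lt(med, 13)
})

test_that("drift-free correction leaves the QC CV profile essentially intact", {
  # with >= 8 QCs and span 0.5 the fit must not chase noise: the median
  # QC CV may shrink by at most a third and may not grow by 1 point
  b <- generate_batch(sim_config(seed = 12, n_per_group = 16, drift = "none"))
  cv0 <- median(cv_profile(b$ft, "qc")$cv_values)
  cv1 <- median(cv_profile(quiet(lowess_drift_correct(b$ft)), "qc")$cv_values)
  expect_lt(cv1 - cv0, 1)
  expect_gt(cv1, cv0 * 2 / 3)
})
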