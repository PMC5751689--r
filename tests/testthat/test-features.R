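test_that("the scan recovers a planted (degree, 0.21) group difference", {
  set.seed(7)
  tensor <- make_tensor(20, 20, planted = list(metric = "degree", sparsity = 0.21),
                        effect = 2)
  scan <- group_difference_scan(tensor)
  expect_s3_class(scan, "fnirs_scan")
  expect_equal(scan$chosen_metric, "degree")
  expect_equal(scan$chosen_sparsity, 0.21)
  expect_gte(scan$n_significant, 10)
  expect_equal(nrow(scan$score_table), 4 * 50)
  expect_true(all(scan$p_values$p >= 0 & scan$p_values$p <= 1))
})

test_that("identical groups give p = 1 everywhere and zero scores", {
  base <- make_tensor(3, 3, grid = c(0.1, 0.2), n_channels = 5)
  # make controls exact copies of patients
  wide <- fnirsnet:::tensor_matrix(base)
  wide$x[4:6, ] <- wide$x[1:3, ]
  suppressWarnings(scan <- fnirsnet:::scan_matrix(wide, alpha = 0.05))
  expect_true(all(scan$score_table$n_significant == 0))
  expect_true(all(scan$p_values$p == 1))
})

test_that("vectorised Welch p-values match stats::t.test", {
  set.seed(13)
  x <- matrix(rnorm(30 * 25), 30, 25)
  x[1:12, 1:5] <- x[1:12, 1:5] + 1
  g <- c(rep(TRUE, 12), rep(FALSE, 18))
  p_fast <- fnirsnet:::welch_p_values(x, g)
  p_ref <- apply(x, 2, function(col) t.test(col[g], col[!g])$p.value)
  expect_equal(as.numeric(p_fast), unname(p_ref), tolerance = 1e-12)
})

test_that("null rejection rate sits at the nominal alpha", {
  set.seed(14)
  n_rej <- 0; n_tot <- 0
  for (rep in 1:500) {
    x <- matrix(rnorm(24 * 10), 24, 10)
    p <- fnirsnet:::welch_p_values(x, rep(c(TRUE, FALSE), each = 12))
    n_rej <- n_rej + sum(p < 0.05)
    n_tot <- n_tot + length(p)
  }
  expect_gt(n_rej / n_tot, 0.03)
  expect_lt(n_rej / n_tot, 0.07)
})

test_that("selection is invariant to subject ordering", {
  set.seed(15)
  tensor <- make_tensor(8, 8, grid = c(0.1, 0.2, 0.3), n_channels = 8,
                        planted = list(metric = "clustering", sparsity = 0.2),
                        effect = 1.5, n_shift_channels = 4)
  scan1 <- group_difference_scan(tensor)
  perm <- sample(unique(tensor$subject_id))
  shuffled <- dplyr::arrange(tensor, match(.data$subject_id, perm))
  class(shuffled) <- class(tensor)
  scan2 <- group_difference_scan(shuffled)
  expect_equal(scan1$chosen_metric, scan2$chosen_metric)
  expect_equal(scan1$chosen_sparsity, scan2$chosen_sparsity)
  expect_equal(dplyr::arrange(scan1$score_table, metric, sparsity),
               dplyr::arrange(scan2$score_table, metric, sparsity))
})

test_that("tie-breaking prefers lower sparsity then the metric order", {
  set.seed(16)
  base <- make_tensor(6, 6, grid = c(0.1, 0.3), n_channels = 4)
  wide <- fnirsnet:::tensor_matrix(base)
  # remove all group signal, then plant identical strong shifts at two combos
  pat <- wide$subjects$group == 1L
  for (combo in list(c("global_efficiency", 0.3), c("degree", 0.3))) {
    cols <- wide$index$metric == combo[1] &
      abs(wide$index$sparsity - as.numeric(combo[2])) < 1e-9
    wide$x[pat, cols] <- wide$x[pat, cols] + 50
  }
  scan <- fnirsnet:::scan_matrix(wide, alpha = 0.05)
  expect_equal(scan$chosen_metric, "degree") # metric order breaks the tie
  expect_equal(scan$chosen_sparsity, 0.3)
})

test_that("feature slices have subjects x channels shape and honest errors", {
  set.seed(17)
  tensor <- make_tensor(4, 3, grid = c(0.1, 0.21), n_channels = 6)
  feats <- select_feature_vector(tensor, "degree", 0.21)
  expect_equal(dim(features_matrix(feats)), c(7, 6))
  expect_equal(features_labels(feats), c(rep(1L, 4), rep(-1L, 3)))
  expect_error(select_feature_vector(tensor, "degree", 0.33), "not in the tensor")
  expect_error(select_feature_vector(tensor, "entropy", 0.21))

  # re-stacking every slice reproduces the tensor values
  total <- sum(vapply(c(0.1, 0.21), function(s) {
    sum(vapply(fnirsnet:::metric_names(), function(m) {
      sum(features_matrix(select_feature_vector(tensor, m, s)))
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(total, sum(tensor$value))
})

test_that("scans need two subjects per group", {
  tensor <- make_tensor(1, 5, grid = 0.1, n_channels = 3)
  expect_error(group_difference_scan(tensor), "at least 2 subjects")
})
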