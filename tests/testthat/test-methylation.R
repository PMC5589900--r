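test_that("region averaging takes the unweighted mean, skipping missing", {
  reg <- make_regions(2L)
  # probes at pos 100, 150, 200 fall in R01 ([0,1000)); 2100, 2150 in R02
  man <- make_manifest(paste0("cg", 1:5),
                       pos = c(100L, 150L, 200L, 2100L, 2150L))
  beta <- matrix(c(0.4, 0.6, NA, 0.2, 0.4,
                   0.2, NA, 0.4, 0.8, 0.8), 5, 2,
                 dimnames = list(paste0("cg", 1:5), c("S1", "S2")))
  avg <- dmr_average(beta_matrix(beta), reg, manifest = man)
  expect_equal(avg["R01", "S1"], 0.5)
  expect_equal(avg["R01", "S2"], 0.3)   # (0.2, missing, 0.4)
  expect_equal(avg["R02", "S2"], 0.8)
})

test_that("single-probe regions are excluded with a warning", {
  reg <- make_regions(2L)
  man <- make_manifest(paste0("cg", 1:3), pos = c(100L, 150L, 2100L))
  beta <- matrix(0.5, 3, 2, dimnames = list(paste0("cg", 1:3),
                                            c("S1", "S2")))
  expect_warning(avg <- dmr_average(beta_matrix(beta), reg,
                                    manifest = man),
                 "fewer than 2 probes")
  expect_identical(rownames(avg), "R01")
})

test_that("control stats use the n-1 standard deviation", {
  avg <- matrix(c(0.5, 0.5, 0.5, 0.4, 0.6, NA), 2, 3, byrow = TRUE,
                dimnames = list(c("R01", "R02"), c("N1", "N2", "N3")))
  cs <- compute_control_stats(avg, c("N1", "N2", "N3"))
  expect_equal(cs$mean, c(0.5, 0.5))
  expect_equal(cs$sd[1], 0)
  expect_equal(cs$sd[2], sqrt(0.02), tolerance = 1e-6)  # ~0.1414
  expect_error(compute_control_stats(avg, "N1", tissue = "breast"),
               "breast")
})

test_that("CNA-predicted methylation reproduces the allele-counting model", {
  # normal 2:1 -> 50% regardless of the observed branch
  expect_equal(as.numeric(predicted_methylation(2L, 1L, c(0.1, 0.9))),
               c(0.5, 0.5))
  # 4:1 -> 75:25 or 25:75 depending on the parental branch
  expect_equal(as.numeric(predicted_methylation(4L, 1L, 0.8)), 0.75)
  expect_equal(as.numeric(predicted_methylation(4L, 1L, 0.2)), 0.25)
  # cnnLOH: near zero or fully methylated, whatever the total
  expect_equal(as.numeric(predicted_methylation(2L, 0L, 0.05)), 0)
  expect_equal(as.numeric(predicted_methylation(3L, 0L, 0.95)), 1)
  # high-copy state with retained heterozygosity
  expect_equal(as.numeric(predicted_methylation(14L, 2L, 0.9)), 6 / 7)
  # homozygous deletion has no prediction
  expect_true(is.na(predicted_methylation(0L, 0L, 0.4)))
  # exact 0.5 ties break toward 1 - m and are counted
  p <- predicted_methylation(4L, 1L, 0.5)
  expect_equal(as.numeric(p), 0.75)
  expect_identical(attr(p, "ties"), 1L)
  expect_error(predicted_methylation(4L, 3L, 0.5), "minor")
})

test_that("predicted methylation stays on an allele fraction and is symmetric", {
  for (tot in 1:10) for (m in 0:(tot %/% 2)) {
    x <- seq(0.05, 0.95, by = 0.1)
    p <- as.numeric(predicted_methylation(tot, m, x))
    expect_true(all(p %in% c(m / tot, 1 - m / tot)))
    p_flip <- as.numeric(predicted_methylation(tot, m, 1 - x))
    expect_equal(p_flip, 1 - p)
  }
})

test_that("CNA independence is a strict 3 s.d. band on the deviation", {
  expect_false(call_cna_independent(0.5, 0.5, 0.03))
  expect_true(call_cna_independent(0.62, 0.5, 0.03))   # 4 s.d.
  expect_false(call_cna_independent(0.59, 0.5, 0.03))  # exactly 3 s.d.
  # sd = 0: any real deviation is independent, ulp noise is not
  expect_true(call_cna_independent(0.501, 0.5, 0))
  expect_false(call_cna_independent(0.5 + 1e-15, 0.5, 0))
  expect_true(is.na(call_cna_independent(NA, 0.5, 0.03)))
})

test_that("methylation states partition the observed range", {
  expect_identical(classify_state(0.85, 0.5), "hypermethylated")
  expect_identical(classify_state(0.15, 0.5), "hypomethylated")
  expect_identical(classify_state(0.72, 0.5), "intermediate_gain")
  expect_identical(classify_state(0.28, 0.5), "intermediate_loss")
  expect_identical(classify_state(0.55, 0.5), "normal")
  # exactly one state for every (observed, control) combination
  grid <- expand.grid(obs = seq(0, 1, by = 0.05),
                      ctrl = seq(0.2, 0.8, by = 0.1))
  st <- classify_state(grid$obs, grid$ctrl)
  expect_false(anyNA(st))
  expect_true(all(st %in% c("hypermethylated", "hypomethylated",
                            "intermediate_gain", "intermediate_loss",
                            "normal")))
})

test_that("cnnLOH parent inference follows the germline methylation origin", {
  expect_identical(infer_cnnloh_parent(0.92, "maternal"), "maternal")
  expect_identical(infer_cnnloh_parent(0.05, "maternal"), "paternal")
  expect_identical(infer_cnnloh_parent(0.5, "maternal"), "ambiguous")
  expect_identical(infer_cnnloh_parent(0.92, "paternal"), "paternal")
  expect_identical(infer_cnnloh_parent(0.05, "paternal"), "maternal")
  expect_error(infer_cnnloh_parent(0.9, "none"), "maternal or paternal")
})

test_that("variance explained is the OLS coefficient of determination", {
  expect_equal(as.numeric(variance_explained(c(0.2, 0.5, 0.8),
                                             c(0.2, 0.5, 0.8))), 1)
  # exact affine relation also gives R^2 = 1
  expect_equal(as.numeric(variance_explained(c(0.1, 0.5, 0.9),
                                             c(0, 0.5, 1))), 1)
  # orthogonalized toy vectors: no shared variance
  x <- c(-1, 0, 1, 0)
  y <- c(0, -1, 0, 1)
  expect_lt(as.numeric(variance_explained(y, x)), 1e-12)
  v <- variance_explained(c(0.3, 0.5, 0.7), c(0.5, 0.5, 0.5))
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "degenerate"))
  expect_error(variance_explained(c(0.1, 0.2), c(0.1, 0.2)), "3 paired")
})
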