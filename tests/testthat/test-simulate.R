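small_cfg <- function(...) {
  args <- list(n_tumors = 6L, n_normals = 4L,
               regions = default_regions(8L, 3L, 3L, 3L), seed = 33L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("the generator is deterministic and seed-sensitive", {
  s1 <- simulate_cohort(small_cfg())
  s2 <- simulate_cohort(small_cfg())
  expect_identical(s1$beta$beta, s2$beta$beta)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(small_cfg(seed = 34L))
  expect_false(identical(s1$truth, s3$truth))
})

test_that("a quiet diploid cohort sits exactly at 0.5 over the DMRs", {
  sim <- simulate_cohort(small_cfg(cna_rate = 0, epimutation_rate = 0,
                                   noise_sd = 0, biovar_sd = 0))
  dmr_probes <- sim$manifest$probe_id[
    sim$manifest$region_id %in%
      sim$regions$region_id[sim$regions$klass == "imprinted_dmr"]]
  expect_true(all(sim$beta$beta[dmr_probes, sim$tumors] == 0.5))
  expect_true(all(sim$beta$beta[dmr_probes, sim$normals] == 0.5))
  expect_identical(nrow(sim$segments), 0L)
})

test_that("emitted segments agree with the truth table copy states", {
  sim <- simulate_cohort(small_cfg(cna_rate = 0.6, noise_sd = 0))
  tr <- sim$truth[sim$truth$is_tumor &
                  sim$truth$klass == "imprinted_dmr", ]
  st <- overlap_locus_state(sim$segments, sim$regions[
    sim$regions$klass == "imprinted_dmr", ], sim$anatomy,
    samples = sim$tumors)
  m <- merge(st, tr, by = c("sample_id", "region_id"))
  expect_identical(nrow(m), length(sim$tumors) * 8L)
  expect_identical(m$total_cn.x, m$total_cn.y)
  expect_identical(m$minor_cn.x, m$minor_cn.y)
})

test_that("true betas always equal methylated copies over total copies", {
  sim <- simulate_cohort(small_cfg(cna_rate = 0.7,
                                   epimutation_rate = 0.3))
  tr <- sim$truth[sim$truth$klass == "imprinted_dmr", ]
  expect_equal(tr$true_beta, tr$meth_copies / tr$total_cn)
  expect_true(all(tr$minor_cn <= tr$total_cn - tr$minor_cn))
})

test_that("adding tumors never perturbs existing samples", {
  a <- simulate_cohort(small_cfg(n_tumors = 4L))
  b <- simulate_cohort(small_cfg(n_tumors = 7L))
  expect_identical(a$beta$beta[, a$tumors], b$beta$beta[, a$tumors])
  expect_identical(a$beta$beta[, a$normals], b$beta$beta[, a$normals])
})

test_that("epimutation injection rewrites per-copy states as labelled", {
  cfg0 <- small_cfg(cna_rate = 0.5, epimutation_rate = 0)
  base0 <- draw_copy_truth(cfg0)
  expect_identical(inject_epimutations(base0, cfg0), base0)
  cfg2 <- small_cfg(cna_rate = 0.5, epimutation_rate = 1,
                    noise_sd = 0, biovar_sd = 0)
  base <- draw_copy_truth(cfg2)
  tr <- inject_epimutations(base, cfg2)
  dm <- tr[tr$is_tumor & tr$klass == "imprinted_dmr", ]
  expect_true(all(dm$epimutation != "none"))
  expect_true(all(dm$true_beta[dm$epimutation == "hyper"] == 1))
  expect_true(all(dm$true_beta[dm$epimutation == "hypo"] == 0))
  # intermediate flips exactly one copy: beta moves by exactly 1/total
  base_dm <- base[base$is_tumor & base$klass == "imprinted_dmr", ]
  inter <- dm$epimutation == "intermediate"
  expect_equal(abs(dm$true_beta[inter] - base_dm$true_beta[inter]),
               1 / dm$total_cn[inter])
})

test_that("a hyper epimutation at a diploid locus classifies hypermethylated", {
  cfg <- small_cfg(cna_rate = 0, epimutation_rate = 1,
                   epimutation_kinds = c(hyper = 1, hypo = 0,
                                         intermediate = 0),
                   noise_sd = 0, biovar_sd = 0)
  sim <- simulate_cohort(cfg)
  avg <- dmr_average(sim$beta, sim$regions, manifest = sim$manifest)
  dmr <- sim$regions$region_id[sim$regions$klass == "imprinted_dmr"]
  obs <- avg[dmr, sim$tumors]
  expect_true(all(obs == 1))
  expect_true(all(classify_state(as.vector(obs), 0.5) ==
                  "hypermethylated"))
})

test_that("purity mixes tumor and normal betas linearly", {
  expect_equal(mix_purity(0.9, 0.5, 1), 0.9)
  expect_equal(mix_purity(0.9, 0.5, 0), 0.5)
  expect_equal(mix_purity(1.0, 0.5, 0.722), 0.861)
})

test_that("RRBS counts follow the coverage model and match the array view", {
  cfg <- small_cfg(cna_rate = 0.6, epimutation_rate = 0.3,
                   noise_sd = 0.01, rrbs_mean_coverage = 50)
  sim <- simulate_cohort(cfg)
  rr <- simulate_rrbs_counts(sim, samples = sim$tumors[1:3])
  expect_true(all(rr$meth_count <= rr$total_count))
  expect_true(all(rr$total_count >= 1))
  expect_equal(mean(rr$total_count), 50, tolerance = 0.1)
  # region aggregation across samples correlates with the array view
  dmrs <- sim$regions[sim$regions$klass == "imprinted_dmr", ]
  avg <- dmr_average(sim$beta, dmrs, manifest = sim$manifest)
  arr <- rrb <- numeric(0)
  for (s in sim$tumors[1:3]) {
    v <- aggregate_rrbs_regions(rr[rr$sample == s, ], dmrs,
                                min_coverage = 10L)
    arr <- c(arr, avg[names(v), s])
    rrb <- c(rrb, v)
  }
  ok <- !is.na(rrb)
  expect_gt(suppressWarnings(cor(rrb[ok], arr[ok], method = "spearman")),
            0.9)
})

test_that("invalid simulation configs fail before any generation", {
  expect_error(sim_config(cna_rate = 1.5), "rates")
  expect_error(sim_config(max_total_cn = 1), "max_total_cn")
  expect_error(sim_config(probes_per_region = 1), "probes_per_region")
})
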