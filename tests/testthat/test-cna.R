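test_that("cnnLOH definition: minor zero with at least two total copies", {
  expect_true(is_cnnloh(2L, 0L))
  expect_true(is_cnnloh(14L, 0L))   # most extreme state seen in tumors
  expect_false(is_cnnloh(1L, 0L))
  expect_false(is_cnnloh(2L, 1L))
  # monotone in total for minor = 0
  expect_true(all(is_cnnloh(2:20, 0L)))
})

test_that("baseline ploidy is the length-weighted median total copy number", {
  uni2 <- make_segments("S", "chr1", c(0, 50), c(50, 90), c(2, 2), c(1, 1))
  expect_identical(estimate_baseline_ploidy(uni2), 2L)
  uni4 <- make_segments("S", "chr1", 0, 100, 4, 2)
  expect_identical(estimate_baseline_ploidy(uni4), 4L)
  # 70% of bp at total 2, 30% at total 6
  mix <- make_segments("S", "chr1", c(0, 70), c(70, 100), c(2, 6), c(1, 3))
  expect_identical(estimate_baseline_ploidy(mix), 2L)
  expect_error(estimate_baseline_ploidy(mix[0, ]), "no segments")
})

test_that("baseline ploidy matches a brute-force expanded median", {
  # oracle: expand each segment to unit-length copies and take the first
  # value at which the cumulative count reaches half the genome
  oracle <- function(tot, len) {
    x <- sort(rep(tot, len))
    max(1L, as.integer(floor(x[ceiling(length(x) / 2)] + 0.5)))
  }
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    tot <- sample(0:8, n, TRUE)
    len <- sample(1:30, n, TRUE)
    start <- cumsum(c(0, head(len, -1)))
    seg <- data.frame(sample_id = "S", chrom = "chr1", start = start,
                      end = start + len, total_cn = tot,
                      minor_cn = pmin(tot %/% 2L, tot))
    expect_identical(estimate_baseline_ploidy(seg), oracle(tot, len))
  }
})

test_that("ploidy of a uniformly (k, k/2) genome is k", {
  for (k in c(2L, 4L, 6L, 8L)) {
    seg <- make_segments("S", "chr1", 0, 1000, k, k %/% 2L)
    expect_identical(estimate_baseline_ploidy(seg), k)
  }
})

test_that("boundedness follows the 1 Mb rule with strict internal cutoff", {
  an <- make_anatomy(length_bp = 100e6, cen = c(45e6, 50e6))
  expect_identical(classify_boundedness(0, 5e6, an), "telomere_bound")
  expect_identical(classify_boundedness(44e6, 46e6, an),
                   "centromere_bound")      # overlaps the centromere
  # min distance exactly 1 Mb is still bound; 1 Mb + 1 bp is internal
  expect_identical(classify_boundedness(1e6, 2e6, an), "telomere_bound")
  expect_identical(classify_boundedness(1e6 + 1, 2e6, an), "internal")
  # nearer anchor decides the bound class
  expect_identical(classify_boundedness(50.2e6, 51e6, an),
                   "centromere_bound")
  expect_error(classify_boundedness(0, 10, make_anatomy(), chrom = "chr9"),
               "absent from anatomy")
})

test_that("locus state assignment covers every (sample, region) pair", {
  an <- make_anatomy()
  reg <- make_regions(3L, start = 10e6, width = 1000L, gap = 9000L)
  seg <- make_segments(c("S1", "S1", "S2"), "chr1",
                       c(9e6, 10.005e6, 0),
                       c(10.0005e6, 12e6, 50e5),
                       c(4, 2, 3), c(1, 0, 1))
  st <- overlap_locus_state(seg, reg, an, samples = c("S1", "S2"))
  expect_identical(nrow(st), 6L)
  # S1/R01 covered by the 4:1 segment alone
  r1 <- st[st$sample_id == "S1" & st$region_id == "R01", ]
  expect_identical(c(r1$total_cn, r1$minor_cn), c(4L, 1L))
  expect_false(r1$assumed)
  # S2 has no segment near any region: assumed diploid
  s2 <- st[st$sample_id == "S2", ]
  expect_true(all(s2$assumed) && all(s2$total_cn == 2L))
  expect_true(all(s2$aberration == "normal"))
})

test_that("a 1 bp overlap makes a segment eligible", {
  an <- make_anatomy()
  reg <- make_regions(1L, start = 10e6, width = 1000L)
  seg <- make_segments("S1", "chr1", 10e6 + 999, 12e6, 5, 2)
  st <- overlap_locus_state(seg, reg, an)
  expect_identical(st$total_cn, 5L)
  expect_false(st$assumed)
})

test_that("split regions take the state of the largest-overlap segment", {
  an <- make_anatomy()
  reg <- make_regions(1L, start = 10e6, width = 1000L)
  # 60% covered by 3:1, 40% by 2:0 (abutting at start + 600)
  seg <- make_segments(c("S1", "S1"), "chr1",
                       c(9e6, 10e6 + 600), c(10e6 + 600, 12e6),
                       c(3, 2), c(1, 0))
  st <- overlap_locus_state(seg, reg, an)
  expect_identical(c(st$total_cn, st$minor_cn), c(3L, 1L))
  # tie on overlap length: larger total_cn wins
  seg2 <- make_segments(c("S1", "S1"), "chr1",
                        c(9e6, 10e6 + 500), c(10e6 + 500, 12e6),
                        c(3, 6), c(1, 2))
  st2 <- overlap_locus_state(seg2, reg, an)
  expect_identical(st2$total_cn, 6L)
})

test_that("locus states are labelled with aberration and cnnLOH flags", {
  an <- make_anatomy()
  reg <- make_regions(4L, start = 10e6, width = 1000L, gap = 4e6)
  seg <- make_segments(rep("S1", 4), "chr1",
                       reg$start - 100, reg$end + 100,
                       c(2, 2, 1, 7), c(1, 0, 0, 3))
  st <- overlap_locus_state(seg, reg, an)
  expect_identical(st$aberration,
                   c("normal", "cnnloh", "deletion", "amplification"))
  expect_identical(st$cnnloh, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(st$boundedness[1], "not_applicable")
})

test_that("CNA size summary separates internal from bound aberrations", {
  an <- make_anatomy()
  reg <- make_regions(1L, start = 20e6, width = 1000L)
  st <- overlap_locus_state(
    make_segments(c("S1", "S2"), "chr1",
                  c(19e6, 0), c(27e6, 40e6), c(5, 4), c(1, 1)),
    reg, an, samples = c("S1", "S2"))
  tab <- cna_size_summary(st)
  expect_identical(sort(tab$boundedness), c("internal", "telomere_bound"))
  expect_lt(tab$mean_length_bp[tab$boundedness == "internal"],
            tab$mean_length_bp[tab$boundedness == "telomere_bound"])
  expect_equal(attr(tab, "fraction_internal_smaller"), 1.0)
})

test_that("internal CNAs drawn smaller than bound ones give fraction near 1", {
  set.seed(21)
  an <- make_anatomy(length_bp = 200e6, cen = c(95e6, 100e6))
  reg <- make_regions(5L, start = 20e6, width = 1000L, gap = 15e6)
  rows <- list()
  for (i in 1:40) {
    r <- sample(nrow(reg), 1)
    internal <- runif(1) < 0.5
    if (internal) {
      len <- runif(1, 1e6, 10e6)
      start <- reg$start[r] - len / 2
      end <- start + len
    } else {
      start <- 0            # telomere-bound: runs out to the chromosome end
      end <- reg$end[r]
    }
    rows[[i]] <- data.frame(sample_id = paste0("S", i), chrom = "chr1",
                            start = start, end = end,
                            total_cn = sample(3:8, 1), minor_cn = 1L)
  }
  seg <- do.call(rbind, rows)
  st <- overlap_locus_state(seg, reg, an,
                            samples = unique(seg$sample_id))
  tab <- cna_size_summary(st)
  frac <- attr(tab, "fraction_internal_smaller")
  expect_gte(frac, 0.99)
})
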