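mk_cm <- function(counts, assays, replicates) {
  samples <- data.frame(sample = colnames(counts), assay = assays,
                        replicate = replicates, stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}

test_that("count matrix construction validates its inputs", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  cm <- mk_cm(m, c("T0", "control"), c("R1", "R1"))
  expect_s3_class(cm, "CountMatrix")
  expect_error(mk_cm(matrix(1:4, 2, 2, dimnames = list(c("g1", "g1"),
                                                       c("a", "b"))),
                     c("T0", "control"), c("R1", "R1")), "unique")
  expect_error(mk_cm(m, c("T0", "weird"), c("R1", "R1")), "assay")
  m2 <- m; m2[1] <- -1
  expect_error(mk_cm(m2, c("T0", "control"), c("R1", "R1")), "non-negative")
})

test_that("QC filter applies the published removal rules in order", {
  counts <- rbind(
    keep1  = c(5000, 400, 380, 200, 150),
    zeroct = c(5000, 0, 380, 200, 150),    # 0 in a control sample
    lowrep = c(5000, 400, 99, 200, 150),   # < 100 reads in one sample
    plasm  = c(50001, 400, 380, 200, 150), # over-represented in plasmid
    keep2  = c(4000, 300, 310, 500, 900),
    keep3  = c(3000, 350, 340, 220, 260))
  colnames(counts) <- c("plasmid", "control_R1", "control_R2", "IFNg_R1",
                        "IFNg_R2")
  cm <- mk_cm(counts, c("plasmid", "control", "control", "IFNg", "IFNg"),
              c("R0", "R1", "R2", "R1", "R2"))
  out <- qc_filter(cm, reference_assays = "control")
  expect_setequal(rownames(out$counts$counts), c("keep1", "keep2", "keep3"))
  expect_equal(out$log$rule[out$log$guide_id == "zeroct"], "zero_in_control")
  expect_equal(out$log$rule[out$log$guide_id == "lowrep"], "min_reads")
  expect_equal(out$log$rule[out$log$guide_id == "plasm"],
               "plasmid_overrepresented")
  # the 3-fold control-difference rule is opt-in
  counts2 <- rbind(a = c(1000, 100, 400), b = c(1000, 200, 220))
  colnames(counts2) <- c("plasmid", "control_R1", "control_R2")
  cm2 <- mk_cm(counts2, c("plasmid", "control", "control"),
               c("R0", "R1", "R2"))
  out2 <- qc_filter(cm2, min_reads = NULL, max_control_fold = 3)
  expect_equal(rownames(out2$counts$counts), "b")
  expect_equal(out2$log$rule, "control_fold_difference")
  expect_error(qc_filter(cm2, min_reads = 1e6), "every guide")
})

test_that("RPM normalization reproduces the printed formula exactly", {
  counts <- matrix(c(500, 999500, 250, 999750), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- normalize_rpm(counts)
  expect_equal(norm["g1", "s1"], 500 / 1e6 * 1e6 + 1)  # = 501
  expect_equal(norm["g1", "s1"], 501)
  # sum(norm_rpm - 1) is exactly 1e6 per sample
  expect_equal(colSums(norm - 1), c(s1 = 1e6, s2 = 1e6), tolerance = 1e-9)
  set.seed(61)
  big <- matrix(rpois(3000, 400), 300, 10,
                dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:10)))
  expect_true(all(abs(colSums(normalize_rpm(big) - 1) - 1e6) < 1))
  expect_error(normalize_rpm(matrix(0, 2, 1,
                                    dimnames = list(c("a", "b"), "s"))),
               "zero total")
})

test_that("l2fc is zero for identical columns and shifts by 1 on doubling", {
  set.seed(62)
  counts <- matrix(rpois(40, 300), 20, 2,
                   dimnames = list(sprintf("g%02d", 1:20), c("t", "r")))
  counts[, 2] <- counts[, 1]
  cm <- mk_cm(counts, c("IFNg", "control"), c("R1", "R1"))
  fc <- normalize_and_l2fc(cm, "t", "r")
  expect_equal(fc$l2fc, rep(0, 20))
  # doubling a guide's treated norm_rpm raises its l2fc by exactly 1
  norm <- normalize_rpm(cm)
  g <- "g05"
  l1 <- log2(norm[g, "t"] / norm[g, "r"])
  l2 <- log2(2 * norm[g, "t"] / norm[g, "r"])
  expect_equal(l2 - l1, 1)
})

test_that("EB z-scores center controls exactly and recover homoscedastic sd", {
  set.seed(63)
  n <- 400L
  l2fc <- rnorm(n, mean = 3)             # constant offset, removed by centering
  abun <- rep(500, n)
  is_ctrl <- seq_len(n) <= 50
  z <- eb_zscore(l2fc, abun, is_ctrl)
  # library smaller than the window: one global sd, control z mean exactly 0
  expect_equal(mean(z[is_ctrl]), 0, tolerance = 1e-12)
  # a guide whose l2fc equals the control mean gets z = 0
  l2fc2 <- l2fc; l2fc2[60] <- mean(l2fc[is_ctrl])
  z2 <- eb_zscore(l2fc2, abun, is_ctrl)
  expect_equal(z2[60], 0, tolerance = 1e-12)
  # invariance under adding a constant to all fold changes
  z3 <- eb_zscore(l2fc + 5, abun, is_ctrl)
  expect_equal(z3, z, tolerance = 1e-12)

  # homoscedastic guides: implied sd within 5% of the pooled sample sd
  set.seed(64)
  n <- 2000L
  l2fc <- rnorm(n, sd = 0.7)
  abun <- rlnorm(n, log(500), 0.4)
  is_ctrl <- seq_len(n) <= 100
  z <- eb_zscore(l2fc, abun, is_ctrl)
  centered <- l2fc - mean(l2fc[is_ctrl])
  sd_implied <- abs(centered / z)
  expect_lt(abs(median(sd_implied, na.rm = TRUE) - sd(centered)) / sd(centered),
            0.05)
  expect_true(all(is.finite(z)))
  expect_error(eb_zscore(l2fc, abun, rep(FALSE, n)), "at least 20")
})

test_that("element aggregation computes normZ, p and BH-FDR correctly", {
  gz <- data.frame(guide_id = sprintf("g%d", 1:4), z = rep(1, 4))
  mp <- data.frame(guide_id = sprintf("g%d", 1:4), element = "E1")
  agg <- aggregate_elements(gz, mp)
  expect_equal(agg$normZ, 2)             # 4 / sqrt(4)
  expect_equal(agg$n_guides, 4L)
  # single-guide element keeps its z
  gz1 <- data.frame(guide_id = "g9", z = -2.5)
  agg1 <- aggregate_elements(gz1, data.frame(guide_id = "g9", element = "S"))
  expect_equal(agg1$normZ, -2.5)
  expect_equal(agg1$p, 2 * pnorm(-2.5))
  # BH adjustment matches the brute-force oracle on 10 elements
  set.seed(65)
  gz10 <- data.frame(guide_id = sprintf("g%02d", 1:10), z = rnorm(10, 0, 2))
  mp10 <- data.frame(guide_id = sprintf("g%02d", 1:10),
                     element = sprintf("E%02d", 1:10))
  agg10 <- aggregate_elements(gz10, mp10)
  expect_equal(agg10$fdr, oracle_bh(agg10$p))
  expect_true(all(agg10$fdr >= 0 & agg10$fdr <= 1))
  # empty mapping gives an empty result
  expect_equal(nrow(aggregate_elements(gz10, mp10[0, ])), 0L)
})

test_that("classification separates LOF, GOF, SOF and neutral calls", {
  prolif <- data.frame(element = c("lof", "sof", "gof", "neu"),
                       normZ = c(6, 5, -4, 0.2))
  facs <- data.frame(element = c("lof", "sof", "gof", "neu"),
                     normZ = c(5, 0, 0.1, -0.1))
  bench_lof <- list(prolif = c(4.8, 5.2, 5.0, 6.1, 5.4),
                    facs = c(4.6, 5.0, 4.8, 5.2, 5.1))
  bench_gof <- list(prolif = c(-3.1, -3.5, -3.3, -4.0))
  calls <- classify_variants(prolif, facs, bench_lof, bench_gof)
  got <- setNames(calls$call, calls$element)
  expect_equal(got[["lof"]], "LOF")
  expect_equal(got[["sof"]], "SOF")   # scores in proliferation but not FACS
  expect_equal(got[["gof"]], "GOF")   # depleted; FACS support not required
  expect_equal(got[["neu"]], "neutral")
  # without FACS data, calls degrade to proliferation-only
  expect_message(calls2 <- classify_variants(prolif, NULL, bench_lof,
                                             bench_gof),
                 "degrades")
  expect_equal(setNames(calls2$call, calls2$element)[["sof"]], "LOF")
})

test_that("replicates average into guide z before aggregation", {
  truth <- flat_truth(30, n_lof = 2, n_controls = 60, seed = 71)
  cfg <- sim_config(seed = 71)
  cm <- simulate_screen_counts(truth, cfg)
  res <- run_screen(cm, "IFNg", "control",
                    truth$guide_id[truth$class == "control"],
                    stats::na.omit(truth[, c("guide_id", "element")]))
  expect_equal(sort(unique(res$guide_scores$replicate)), c("R1", "R2"))
  g <- res$guide_scores$guide_id[1]
  zr <- res$guide_scores$z[res$guide_scores$guide_id == g]
  expect_equal(res$guide_z_mean$z[res$guide_z_mean$guide_id == g], mean(zr))
  expect_equal(nrow(res$element_scores), 30L)
})
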