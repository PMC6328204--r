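test_that("median-of-ratios size factors match hand computation and DESeq2", {
  # identical columns: symmetry forces factors of 1
  m <- matrix(c(5, 10, 20, 5, 10, 20), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(computeSizeFactors(m)), c(1, 1))

  # column B = 2 x column A: geometric-mean reference gives (1/sqrt(2), sqrt(2))
  m2 <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(computeSizeFactors(m2)), c(1 / sqrt(2), sqrt(2)))

  # a zero anywhere removes the feature from the reference set
  m3 <- rbind(m2, g4 = c(0, 1000))
  expect_equal(computeSizeFactors(m3), computeSizeFactors(m2))

  # independent cross-check on a random matrix
  set.seed(42)
  m4 <- matrix(rpois(600, 50) + 1, ncol = 6,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  expect_equal(unname(computeSizeFactors(m4)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m4)),
               tolerance = 1e-10)

  expect_error(computeSizeFactors(matrix(c(0, 1, 1, 0), 2,
                                         dimnames = list(c("a", "b"), c("x", "y")))),
               "nonzero")
})

test_that("size factors are scale-equivariant in any one sample", {
  set.seed(7)
  m <- matrix(rpois(300, 40) + 1, ncol = 3,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
  sf <- computeSizeFactors(m)
  for (k in c(2, 5)) {
    m2 <- m; m2[, 2] <- m[, 2] * k
    sf2 <- computeSizeFactors(m2)
    expect_equal(unname(sf2[2] / sf[2]), unname(k * (sf2[1] / sf[1])),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces hand values and a brute-force oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  bruteBH <- function(p) {            # sort, scale, cumulative-min, unsort
    o <- order(p); m <- length(p)
    scaled <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(scaled)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bhAdjust(p), bruteBH(p))
  }
})

test_that("NB Wald test is calibrated on null counts and detects planted effects", {
  set.seed(314)
  # null: no effects, 200 features
  cfg <- simulationConfig(seed = 314, n_features_mirna = 200,
                          n_planted_concordant_mirna = 0,
                          n_planted_single_cohort_mirna = 0)
  sim <- simulateMirnaCohorts(cfg)
  de <- deTest(sim$cohort1)
  expect_gt(mean(de$p_value < 0.05), 0.02)
  expect_lt(mean(de$p_value < 0.05), 0.09)

  # planted 4-fold feature, 4 vs 4 samples, dispersion 0.05
  set.seed(99)
  mu <- rlnorm(200, log(100), 1.2)
  planted <- which.max(mu > 50)
  fc <- rep(1, 200); fc[planted] <- 4
  mk <- function() {
    mu_mat <- outer(mu, rep(1, 8))
    mu_mat[, 5:8] <- mu_mat[, 5:8] * fc
    m <- matrix(rnbinom(1600, mu = mu_mat, size = 1 / 0.05), nrow = 200,
                dimnames = list(paste0("f", 1:200), paste0("s", 1:8)))
    OmicsCounts(m, rep(c("naive", "stressed"), each = 4), "c1", "mirna")
  }
  de2 <- deTest(mk())
  expect_lt(de2$p_value[planted], 0.05)
  expect_gt(de2$log2fc[planted], 1)
})

test_that("all-zero features get log2fc 0, p 1 and do not enter the BH m", {
  set.seed(5)
  m <- matrix(rpois(500, 30) + 1, nrow = 100)
  m[7, ] <- 0L
  dimnames(m) <- list(paste0("f", 1:100), paste0("s", 1:5))
  oc <- OmicsCounts(m, c("naive", "naive", "stressed", "stressed", "stressed"),
                    "c1", "mirna")
  de <- deTest(oc)
  expect_equal(de$log2fc[7], 0)
  expect_equal(de$p_value[7], 1)
  expect_equal(de$direction[7], "none")
  expect_equal(de$adj_p[-7], bhAdjust(de$p_value[-7]))
})

test_that("single-group input is rejected", {
  m <- matrix(rpois(40, 10) + 1, nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
  oc <- OmicsCounts(m, rep("naive", 4), "c1", "mirna")
  expect_error(deTest(oc), "both a naive and a stressed group")
})

test_that("concordance rule applies fold-change, p and sign conditions", {
  one <- function(l1, l2, p1, p2) {
    suppressMessages(concordantMirnaCandidates(
      deRecord("mir-9-5p", l1, p1), deRecord("mir-9-5p", l2, p2)))
  }
  expect_equal(one(0.6, 0.8, 0.01, 0.03)$direction, "up")
  expect_equal(nrow(one(0.6, -0.8, 0.01, 0.01)), 0)    # sign disagreement
  expect_equal(nrow(one(0.5, 0.5, 0.049, 0.049)), 1)   # inclusive lfc boundary
  expect_equal(nrow(one(0.5, 0.5, 0.05, 0.049)), 0)    # strict p boundary
  expect_equal(nrow(one(0.4, 0.8, 0.01, 0.01)), 0)     # below lfc_min in one
})

test_that("cohort merging normalizes ids and warns on empty intersection", {
  d1 <- deRecord(c("mmu-miR-29a-5p", "mmu-miR-7-3p"), c(0.9, 0.8), c(0.01, 0.2))
  d2 <- deRecord(c("mir-29a-5p", "mir-375-3p"), c(0.7, 0.9), c(0.02, 0.01))
  expect_message(cand <- concordantMirnaCandidates(d1, d2), "skipped")
  expect_equal(cand$mirna_id, "mir-29a-5p")
  expect_warning(
    suppressMessages(concordantMirnaCandidates(
      deRecord("mir-1-5p", 1, 0.01), deRecord("mir-2-5p", 1, 0.01))),
    "no shared")
})

test_that("candidate set is contained in both per-cohort DE sets", {
  sim <- simulateMirnaCohorts(tinyConfig(seed = 21))
  de1 <- deTest(sim$cohort1); de2 <- deTest(sim$cohort2)
  cand <- suppressMessages(concordantMirnaCandidates(de1, de2))
  de_set <- function(de) de$feature_id[de$p_value < 0.05 & abs(de$log2fc) >= 0.5]
  expect_true(all(cand$mirna_id %in% intersect(de_set(de1), de_set(de2))))
})

test_that("mRNA significance filter honours the raw/adjusted switch", {
  rec <- deRecord("GENE1", 1.2, 0.01)
  rec$adj_p <- 0.20
  expect_equal(nrow(filterDeMrna(rec, use_adjusted = TRUE)), 0)
  out <- filterDeMrna(rec, use_adjusted = FALSE)
  expect_equal(out$feature_id, "GENE1")
  expect_equal(out$direction, "up")
  expect_equal(nrow(filterDeMrna(rec[0, , drop = FALSE])), 0)
})
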