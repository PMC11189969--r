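test_that("pressure maps validate their grid and pressures", {
  expect_error(pressure_map(tibble::tibble(x = 1, y = 1, pressure = -2)),
               ">= 0")
  bad <- tibble::tibble(x = c(0, 1, 3), y = 0, pressure = 1)
  expect_error(pressure_map(bad), "uniform")
  ok <- pressure_map(tibble::tibble(x = c(0, 5, 10), y = 0, pressure = 1:3))
  expect_s3_class(ok, "pressure_map")
})

test_that("the two-lobed map partitions into the expected bands", {
  pm <- make_pressure_map(peak_heel = 121, peak_forefoot = 107, seed = 3)
  pr <- partition_regions(pm, region_scheme("SEVEN"))
  on <- !is.na(pr$region)
  # masks cover the loaded footprint and are disjoint by construction
  expect_true(all(!is.na(pr$region[pr$pressure > 0])))
  # the heel lobe peak cell sits in a heel region
  top_heel <- which.max(ifelse(pr$y < 0.3 * max(pr$y), pr$pressure, -Inf))
  expect_true(as.character(pr$region[top_heel]) %in%
                c("medial heel", "lateral heel"))
  # the forefoot lobe peak sits in a forefoot region
  top_fore <- which.max(ifelse(pr$y > 0.55 * max(pr$y), pr$pressure, -Inf))
  expect_match(as.character(pr$region[top_fore]), "forefoot")
  # heel-dominant map peaks in the heel band overall
  expect_true(pr$y[which.max(pr$pressure)] < 0.35 * max(pr$y[on]))
})

test_that("a uniform rectangle yields region areas near the band fractions", {
  df <- expand.grid(x = seq(-40, 40, by = 2), y = seq(0, 240, by = 2))
  df$pressure <- 1
  pm <- pressure_map(df, heel = c(0, 0), toe_direction = c(0, 1))
  pr <- partition_regions(pm, region_scheme("SEVEN"))
  frac <- prop.table(table(pr$region))
  # longitudinal bands: heel 0.30, midfoot 0.30, forefoot 0.25, toes 0.15
  expect_equal(unname(frac[["medial heel"]] + frac[["lateral heel"]]), 0.30,
               tolerance = 0.02)
  expect_equal(unname(frac[["midfoot"]]), 0.30, tolerance = 0.02)
  # forefoot columns split 0.40 / 0.30 / 0.30 of the forefoot+toe width;
  # hallux takes the medial third of the toe band
  expect_lt(abs(frac[["medial forefoot"]] - 0.25 * 0.40), 0.01)
  expect_lt(abs(frac[["hallux"]] - 0.15 / 3), 0.01)
})

test_that("SEVEN and EIGHT schemes differ only in the midfoot split", {
  pm <- make_pressure_map(seed = 3)
  p7 <- partition_regions(pm, region_scheme("SEVEN"))
  p8 <- partition_regions(pm, region_scheme("EIGHT"))
  r7 <- as.character(p7$region); r8 <- as.character(p8$region)
  mid <- !is.na(r7) & r7 == "midfoot"
  expect_true(all(r8[mid] %in% c("medial midfoot", "lateral midfoot")))
  expect_identical(r7[!mid], r8[!mid])
})

test_that("region peaks equal the brute-force per-mask maximum", {
  pm <- make_pressure_map(seed = 5)
  pr <- partition_regions(pm, region_scheme("EIGHT"))
  pk <- region_peaks(pr)
  for (i in seq_len(nrow(pk))) {
    v <- pr$pressure[!is.na(pr$region) & pr$region == pk$region[i]]
    expect_identical(pk$peak_kpa[i], max(v))
  }
  # constant map: every region peak equals the constant
  prc <- pr
  prc$pressure[!is.na(prc$region)] <- 100
  expect_true(all(region_peaks(prc)$peak_kpa == 100))
})

test_that("a single hot cell registers only in its own heel region", {
  df <- expand.grid(x = seq(-30, 30, by = 5), y = seq(0, 200, by = 5))
  df$pressure <- 10
  df$pressure[df$x == -10 & df$y == 20] <- 200  # medial heel, right foot
  pm <- pressure_map(df, heel = c(0, 0), toe_direction = c(0, 1))
  pk <- region_peaks(pm, region_scheme("SEVEN"))
  expect_equal(pk$peak_kpa[pk$region == "medial heel"], 200)
  expect_true(all(pk$peak_kpa[pk$region != "medial heel"] == 10))
})

test_that("paired comparison selects its branch from the normality gate", {
  # identical samples: degenerate Wilcoxon branch with p = 1
  same <- c(3, 5, 8, 2, 7)
  res <- compare_paired(same, same)
  expect_equal(res$p_value, 1)
  expect_equal(res$test, "wilcoxon")
  # near-normal differences, n = 12: paired-t branch, statistic by hand
  set.seed(41)
  d <- rnorm(12, mean = 0.5)
  a <- rnorm(12, 50, 5)
  res_t <- compare_paired(a + d, a)
  expect_equal(res_t$test, "paired-t")
  expect_equal(res_t$statistic, mean(d) / (sd(d) / sqrt(12)), tolerance = 1e-12)
  expect_gt(res_t$normality_p, 0.05)
  # branch selection is a pure function of the Shapiro p and alpha
  res_w <- compare_paired(a + d, a, alpha = res_t$normality_p + 1e-6)
  expect_equal(res_w$test, "wilcoxon")
})

test_that("the exact Wilcoxon p matches the sign-enumeration oracle", {
  d <- 1:6
  res <- compare_paired(d, rep(0, 6), test = "wilcoxon")
  # oracle: enumerate all 2^6 sign assignments of the ranks
  ranks <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  W <- signs %*% ranks
  w_obs <- sum(ranks)
  p_exact <- 2 * mean(W >= w_obs)
  expect_equal(p_exact, 0.03125)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("agreement reproduces its closed forms", {
  m <- c(91, 113, 45, 60, 78, 102, 55, 88)
  expect_equal(agreement(m, m)$pearson_r, 1)
  expect_equal(agreement(m, m)$offset, 0)
  sh <- agreement(m, m + 10)
  expect_equal(sh$pearson_r, 1)
  expect_equal(sh$offset, 10)
  expect_equal(sh$loa_lower, 10)
  expect_equal(sh$loa_upper, 10)
  set.seed(42)
  p <- m + rnorm(8, 5, 8)
  ag <- agreement(m, p)
  r_direct <- sum((m - mean(m)) * (p - mean(p))) /
    sqrt(sum((m - mean(m))^2) * sum((p - mean(p))^2))
  expect_equal(ag$pearson_r, r_direct, tolerance = 1e-12)
  d <- p - m
  expect_equal(ag$offset, mean(d))
  expect_equal(ag$loa_upper, mean(d) + 1.96 * sd(d))
  expect_lte(ag$loa_lower, ag$offset)
  expect_gte(ag$loa_upper, ag$offset)
  expect_error(agreement(rep(1, 5), 1:5), "variance")
  # offset shifts by exactly +c under a constant added to predicted
  ag2 <- agreement(m, p + 3.5)
  expect_equal(ag2$offset, ag$offset + 3.5)
})
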