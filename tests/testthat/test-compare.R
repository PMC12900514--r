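test_that("envelope difference resolves the three canonical cases", {
  a <- fake_aggregate(mean = 4, min = 3, max = 5)
  b <- fake_aggregate(mean = 1.5, min = 1, max = 2, condition = "b")
  expect_equal(envelope_difference(a, b), 1)          # A wholly above B
  a2 <- fake_aggregate(mean = 2.5, min = 1, max = 4)
  b2 <- fake_aggregate(mean = 4.5, min = 3, max = 6, condition = "b")
  expect_equal(envelope_difference(a2, b2), 0)        # envelopes overlap
  a3 <- fake_aggregate(mean = 1.5, min = 1, max = 2)
  b3 <- fake_aggregate(mean = 5, min = 4, max = 6, condition = "b")
  expect_equal(envelope_difference(a3, b3), -2)       # B wholly above A
})

test_that("envelope difference is antisymmetric and conservative", {
  set.seed(17)
  for (i in 1:100) {
    L <- 50L
    reps_a <- matrix(runif(3 * L, 0, 10), ncol = 3)
    reps_b <- matrix(runif(3 * L, 0, 10), ncol = 3)
    mk <- function(m, cond) fake_aggregate(rowMeans(m),
                                           do.call(pmin, asplit(m, 2)),
                                           do.call(pmax, asplit(m, 2)), cond)
    a <- mk(reps_a, "a"); b <- mk(reps_b, "b")
    d <- envelope_difference(a, b)
    expect_equal(envelope_difference(b, a), -d)
    expect_true(all(abs(d) <= abs(a$mean - b$mean) + 1e-12))
  }
})

test_that("log2 ratio is exact off-mask and respects the c_min rule", {
  L <- 4L
  a <- fake_aggregate(mean = c(8, 8, 8, 8))
  b <- fake_aggregate(mean = c(8, 2, 8, 8), condition = "b")
  counts_a <- list(rep(10L, L), rep(10L, L))
  counts_b <- list(c(10L, 10L, 4L, 10L), rep(10L, L))
  out <- log2_ratio(a, b, counts_a, counts_b, c_min = 5)
  expect_equal(out$mask, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$ratio, c(0, 2, NA, 0))
})

test_that("a position with every count at c_min - 1 is masked", {
  L <- 3L
  a <- fake_aggregate(mean = rep(1, L))
  b <- fake_aggregate(mean = rep(1, L), condition = "b")
  counts <- list(c(5L, 4L, 5L), c(5L, 4L, 5L))
  out <- log2_ratio(a, b, counts, counts, c_min = 5)
  expect_equal(out$mask, c(FALSE, TRUE, FALSE))
})

test_that("surviving zero-frequency positions are force-masked with a warning", {
  a <- fake_aggregate(mean = c(1, 0))
  b <- fake_aggregate(mean = c(1, 1), condition = "b")
  counts <- list(c(10L, 10L))
  expect_warning(out <- log2_ratio(a, b, counts, counts, c_min = 5),
                 "force-masking")
  expect_true(out$mask[2])
})

test_that("the masked-position set equals brute-force rule evaluation", {
  set.seed(23)
  L <- 40L
  counts_a <- replicate(3, sample(0:12, L, replace = TRUE), simplify = FALSE)
  counts_b <- replicate(3, sample(0:12, L, replace = TRUE), simplify = FALSE)
  a <- fake_aggregate(mean = runif(L, 1, 2))
  b <- fake_aggregate(mean = runif(L, 1, 2), condition = "b")
  out <- log2_ratio(a, b, counts_a, counts_b, c_min = 5)
  brute <- vapply(seq_len(L), function(x)
    min(vapply(c(counts_a, counts_b), `[`, numeric(1), x)) < 5, logical(1))
  expect_equal(out$mask, brute)
  expect_true(all(is.na(out$ratio[out$mask])))
  expect_true(all(!is.na(out$ratio[!out$mask])))
})

test_that("identical replicate sets give t = 0, p = 1 in every region", {
  ann <- default_annotation()
  set.seed(2)
  profs <- lapply(1:3, function(i)
    profile_from_counts(sample(0:3, 6859, replace = TRUE),
                        replicate = paste0("rep", i)))
  rs <- region_stats(profs, profs, ann)
  expect_equal(rs$t, rep(0, 7))
  expect_equal(rs$p, rep(1, 7))
  expect_equal(rs$ratio_ab, rep(1, 7))
})

test_that("region sums of each replicate add up to one million", {
  ann <- default_annotation()
  set.seed(3)
  profs <- lapply(1:3, function(i)
    profile_from_counts(sample(0:3, 6859, replace = TRUE)))
  rs <- region_stats(profs, profs, ann)
  per_rep <- Reduce(`+`, rs$sums_a)
  expect_equal(unname(per_rep), rep(1e6, 3))
})

test_that("Welch statistics match the textbook formula on hand-built sums", {
  # regions engineered so condition A sums are (10,11,12) and B (13,14,15)
  # in freq units x 1e-6; verify t,p against the direct Welch computation
  a <- c(10, 11, 12); b <- c(13, 14, 15)
  ann <- rdna_annotation(data.frame(name = c("r1", "r2"),
                                    start = c(1, 3), end = c(2, 4)))
  mkp <- function(n1) profile_from_counts(c(n1, 0L, 100L - n1, 0L))
  profs_a <- lapply(c(10L, 11L, 12L), mkp)
  profs_b <- lapply(c(13L, 14L, 15L), mkp)
  rs <- region_stats(profs_a, profs_b, ann)
  # oracle: Welch t from first principles
  welch_t <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  nu <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  welch_p <- 2 * pt(-abs(welch_t), nu)
  expect_equal(rs$t[1], welch_t, tolerance = 1e-12)
  expect_equal(rs$p[1], welch_p, tolerance = 1e-12)
  expect_equal(rs$stars[1], "*")
})

test_that("single-replicate conditions report sums but no test", {
  ann <- rdna_annotation(data.frame(name = "all", start = 1, end = 4))
  rs <- region_stats(list(profile_from_counts(c(1L, 1L, 1L, 1L))),
                     list(profile_from_counts(c(2L, 0L, 1L, 1L))), ann)
  expect_true(is.na(rs$t))
  expect_true(is.na(rs$p))
  expect_equal(rs$mean_a, 1e6)
})

test_that("star coding follows the 0.05/0.01/0.005 thresholds", {
  ps <- c(0.04, 0.009, 0.004, 0.2)
  labs <- c("*", "**", "***", "ns")
  ann <- default_annotation()
  # star_label is internal; exercise it through fold_change_stats instead
  df <- data.frame(condition = rep(c("a", "b"), each = 3),
                   replicate = rep(paste0("r", 1:3), 2),
                   probe = "x", ratio = c(1, 1.01, 0.99, 5, 5.05, 4.95))
  fc <- fold_change_stats(df, reference = "a")
  expect_equal(fc$stars[fc$condition == "b"],
               ifelse(fc$p[fc$condition == "b"] < 0.005, "***",
                      ifelse(fc$p[fc$condition == "b"] < 0.01, "**",
                             ifelse(fc$p[fc$condition == "b"] < 0.05, "*", "ns"))))
})

test_that("a uniform profile has the straight-line CDF x/L", {
  p <- profile_from_counts(rep(1L, 10))
  cp <- cdf_profile(list(p))
  expect_equal(cp$mean, (1:10) / 10)
  expect_equal(cp$median_position, 5L)
})

test_that("CDFs are nondecreasing, end at 1 and have a valid envelope", {
  set.seed(6)
  profs <- lapply(1:3, function(i)
    profile_from_counts(sample(0:5, 100, replace = TRUE)))
  cp <- cdf_profile(profs)
  expect_true(all(diff(cp$mean) >= -1e-12))
  expect_equal(cp$mean[100], 1)
  expect_true(all(cp$min <= cp$mean + 1e-12 & cp$mean <= cp$max + 1e-12))
  expect_error(cdf_profile(list(profile_from_counts(rep(0L, 5)))), "all-zero")
})

test_that("shifting a profile rightward moves the median by the shift", {
  set.seed(9)
  base <- c(sample(1:5, 60, replace = TRUE), rep(0L, 40))
  k <- 7L
  shifted <- c(rep(0L, k), base[1:(100 - k)])
  ca <- cdf_profile(list(profile_from_counts(base)))
  cb <- cdf_profile(list(profile_from_counts(shifted)))
  sh <- cdf_shift(cb, ca)
  expect_equal(sh$delta_median, k)
  # the shifted (B = rightward) condition has the lower CDF everywhere
  expect_lte(cdf_shift(cb, ca)$signed_area, 0)
  expect_equal(cdf_shift(ca, cb)$signed_area, -sh$signed_area)
})
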