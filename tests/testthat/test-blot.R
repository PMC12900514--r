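quant_rows <- function(condition, replicate, probes, intensities) {
  data.frame(condition = condition, replicate = replicate, probe = probes,
             intensity = intensities, stringsAsFactors = FALSE)
}

test_that("5S normalization divides by the mean of the two control probes", {
  t <- quant_rows("wt", "rep1",
                  c("5'ETS-1", "5S US", "5S DS"), c(10, 4, 6))
  r <- normalize_to_5s(t)
  expect_equal(r$ratio, 2)
  expect_equal(r$probe, "5'ETS-1")
})

test_that("5S ratios are invariant to per-replicate scale", {
  probes <- c("5'ETS-1", "18S.2", "IGS2", "5S US", "5S DS")
  base <- c(10, 8, 0.5, 4, 6)
  t1 <- quant_rows("wt", "rep1", probes, base)
  t2 <- quant_rows("wt", "rep2", probes, base * 3.7)
  r <- normalize_to_5s(rbind(t1, t2))
  expect_equal(r$ratio[r$replicate == "rep1"], r$ratio[r$replicate == "rep2"])
})

test_that("missing 5S control or zero denominator raise informative errors", {
  t <- quant_rows("wt", "rep1", c("5'ETS-1", "5S US"), c(10, 4))
  expect_error(normalize_to_5s(t), "rep1")
  t0 <- quant_rows("wt", "rep1", c("5'ETS-1", "5S US", "5S DS"), c(10, 0, 0))
  expect_error(normalize_to_5s(t0), "zero 5S")
})

test_that("composite Pol I signal averages member values, permutation-invariant", {
  r <- data.frame(condition = "wt", replicate = "rep1",
                  probe = c("a", "b", "c", "d"), ratio = c(1, 2, 3, 4))
  members <- list("a", "b", "c", "d")
  expect_equal(composite_poli_signal(r, members)$ratio, 2.5)
  expect_equal(composite_poli_signal(r, rev(members))$ratio, 2.5)
  expect_equal(composite_poli_signal(r, list(c("a", "b"), "c"))$ratio,
               mean(c(1.5, 3)))
  expect_error(composite_poli_signal(r, list("a", "zz")), "zz")
})

test_that("window integration matches hand trapezoids", {
  lane <- lane_profile(size = c(60, 100), intensity = c(1, 1))
  expect_equal(window_quant(lane, c(70, 90)), 20)
  zero <- lane_profile(size = c(60, 100), intensity = c(0, 0))
  expect_equal(window_quant(zero, c(70, 90)), 0)
  # piecewise-linear toy trace: vertices at (60,0) (80,2) (100,0)
  tri <- lane_profile(size = c(60, 80, 100), intensity = c(0, 2, 0))
  # hand trapezoid over [70,90]: ((1+2)/2)*10 + ((2+1)/2)*10 = 30
  expect_equal(window_quant(tri, c(70, 90)), 30)
  expect_error(window_quant(tri, c(50, 90)), "outside")
})

test_that("window integration is additive over adjacent windows and monotone in width", {
  set.seed(13)
  lane <- lane_profile(size = seq(50, 150, by = 7), intensity = runif(15, 0, 3))
  whole <- window_quant(lane, c(60, 120))
  expect_equal(window_quant(lane, c(60, 95)) + window_quant(lane, c(95, 120)),
               whole, tolerance = 1e-12)
  expect_gte(whole, window_quant(lane, c(65, 110)))
})

test_that("fold changes and Welch tests versus a reference condition", {
  df <- data.frame(condition = rep(c("wt", "mut"), each = 3),
                   replicate = rep(paste0("r", 1:3), 2),
                   probe = "band",
                   ratio = c(1.0, 1.1, 0.9, 1.5, 1.65, 1.35))
  fc <- fold_change_stats(df, reference = "wt")
  ref <- fc[fc$condition == "wt", ]
  expect_equal(ref$fold_change, 1)
  expect_equal(ref$t, 0)
  expect_equal(ref$p, 1)
  mut <- fc[fc$condition == "mut", ]
  expect_equal(mut$fold_change, 1.5)
  a <- c(1.5, 1.65, 1.35); b <- c(1.0, 1.1, 0.9)
  tt <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  nu <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(mut$t, tt, tolerance = 1e-12)
  expect_equal(mut$p, 2 * pt(-abs(tt), nu), tolerance = 1e-12)
  expect_error(fold_change_stats(df, reference = "nope"), "absent")
})

test_that("exact replicate-wise scaling is recovered as the fold change", {
  df <- data.frame(condition = rep(c("a", "b"), each = 3),
                   replicate = rep(paste0("r", 1:3), 2),
                   probe = "p",
                   ratio = c(2, 3, 4, 3, 4.5, 6))
  fc <- fold_change_stats(df, reference = "a")
  expect_equal(fc$fold_change[fc$condition == "b"], 1.5)
})

test_that("generative fold changes are recovered exactly at zero noise", {
  cat <- default_probe_catalog()
  wt <- preset_model("wt")
  sp <- preset_model("superpol")
  tab <- rbind(
    emit_probe_signals(wt, cat, noise_cv = 0, condition = "wt"),
    emit_probe_signals(sp, cat, noise_cv = 0, condition = "superpol"))
  fc <- fold_change_stats(normalize_to_5s(tab, cat), reference = "wt")
  ss_wt <- steady_state(wt); ss_sp <- steady_state(sp)
  ann <- default_annotation()
  for (pb in c("5'ETS-1", "18S.2", "25S.1")) {
    reg <- cat$target_region[cat$name == pb]
    truth <- region_occupancy(ss_sp, ann, reg) / region_occupancy(ss_wt, ann, reg)
    got <- fc$fold_change[fc$probe == pb & fc$condition == "superpol"]
    expect_equal(got, truth, tolerance = 1e-12)
  }
  expect_equal(fc$fold_change[fc$probe == "IGS2" & fc$condition == "superpol"], 1)
})

test_that("noisy probe signals recover fold changes without bias", {
  cat <- default_probe_catalog()
  wt <- preset_model("wt")
  sp <- preset_model("superpol")
  ann <- default_annotation()
  ss_wt <- steady_state(wt); ss_sp <- steady_state(sp)
  truth <- region_occupancy(ss_sp, ann, "18S") / region_occupancy(ss_wt, ann, "18S")
  set.seed(99)
  reps <- replicate(60, {
    tab <- rbind(
      emit_probe_signals(wt, cat, noise_cv = 0.1, condition = "wt"),
      emit_probe_signals(sp, cat, noise_cv = 0.1, condition = "superpol"))
    fc <- fold_change_stats(normalize_to_5s(tab, cat), reference = "wt")
    c(fc$fold_change[fc$probe == "18S.2" & fc$condition == "superpol"],
      fc$fold_change[fc$probe == "IGS2" & fc$condition == "superpol"])
  })
  expect_lt(abs(mean(reps[1, ]) - truth), 3 * sd(reps[1, ]) / sqrt(60))
  expect_lt(abs(mean(reps[2, ]) - 1), 3 * sd(reps[2, ]) / sqrt(60))
})
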