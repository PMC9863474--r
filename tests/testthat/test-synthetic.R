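# synthetic cohort generator: calibration, reproducibility, fixtures

test_that("cohort specs validate their fields", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n_patients = 1), ">= 2")
  bad <- table1_presets()
  bad$weight <- c(0.5, 0.5, 0.5)
  expect_error(cohort_spec(presets = bad), "sum to 1")
  bad <- table1_presets()
  bad$ratio_sd[1] <- 0
  expect_error(cohort_spec(presets = bad), "positive")
  expect_error(cohort_spec(span_mm = c(60, 20)), "increasing")
  expect_error(cohort_spec(jitter_mm = -1), "non-negative")
  expect_error(cohort_spec(group_sizes = c(1, 1, 1)), "sum to")
})

test_that("the measurement pipeline inverts exactly to the drawn ratios", {
  cs <- sample_cohort(cohort_spec(n_patients = 100, seed = 19))
  m <- measure_cohort(cs$anatomies)
  r <- papvr_ratio(m$d_pv_svd_mm, m$d_pv_azygos_mm)
  expect_equal(r, cs$cohort$drawn_ratio, tolerance = 1e-9)
  expect_true(all(abs(r - cs$cohort$drawn_ratio) < 1e-9))
  # spans are respected too
  expect_equal(m$d_pv_svd_mm + m$d_pv_azygos_mm, cs$cohort$span_mm,
               tolerance = 1e-9)
  expect_true(all(cs$cohort$span_mm >= 20 & cs$cohort$span_mm <= 60))
  # output is flagged as simulated
  expect_true(all(cs$cohort$synthetic))
})

test_that("a near-degenerate preset pins every ratio at its mean", {
  p <- data.frame(label = "WARDEN", ratio_mean = 0.7, ratio_sd = 1e-12,
                  weight = 1)
  cs <- sample_cohort(cohort_spec(n_patients = 20, presets = p, seed = 3))
  m <- measure_cohort(cs$anatomies)
  r <- papvr_ratio(m$d_pv_svd_mm, m$d_pv_azygos_mm)
  expect_true(all(abs(r - 0.7) < 1e-9))
})

test_that("identical spec and seed reproduce the cohort byte for byte", {
  spec <- cohort_spec(n_patients = 25, seed = 29, group_sizes = c(6L, 7L, 12L))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  for (f in c(f1, f2)) {
    cs <- sample_cohort(spec)
    cohort <- measure_cohort(cs$anatomies)
    cohort$actual_procedure <- cs$cohort$actual_procedure
    write_cohort(cohort, f)
  }
  expect_identical(readLines(f1), readLines(f2))
  # different seed changes the draw
  other <- sample_cohort(cohort_spec(n_patients = 25, seed = 30,
                                     group_sizes = c(6L, 7L, 12L)))
  expect_false(identical(other$cohort$drawn_ratio,
                         sample_cohort(spec)$cohort$drawn_ratio))
})

test_that("per-group means and SDs converge to the preset calibration", {
  presets <- table1_presets()
  for (i in seq_len(nrow(presets))) {
    p <- presets[i, ]
    p$weight <- 1
    cs <- sample_cohort(cohort_spec(n_patients = 1000, presets = p,
                                    seed = 40 + i))
    m <- measure_cohort(cs$anatomies)
    r <- papvr_ratio(m$d_pv_svd_mm, m$d_pv_azygos_mm)
    expect_lt(abs(mean(r) - p$ratio_mean), 0.02)
    expect_lt(abs(sd(r) - p$ratio_sd), 0.02)
  }
})

test_that("an exact stratified split sizes the groups deterministically", {
  cs <- sample_cohort(cohort_spec(seed = 31, group_sizes = c(7L, 8L, 15L)))
  tab <- table(factor(cs$cohort$actual_procedure, levels = surgical_labels()))
  expect_equal(as.integer(tab), c(7L, 8L, 15L))
})

test_that("jitter perturbs measured ratios away from the drawn ones", {
  spec <- cohort_spec(n_patients = 40, seed = 37, jitter_mm = 2)
  cs <- sample_cohort(spec)
  m <- measure_cohort(cs$anatomies)
  r <- papvr_ratio(m$d_pv_svd_mm, m$d_pv_azygos_mm)
  expect_gt(max(abs(r - cs$cohort$drawn_ratio)), 1e-6)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("the tubular mesh fixture contains the landmarks as vertices", {
  a <- make_anatomy(pv = c(5, -3, 12), svd = c(5, -3, -8), azy = c(5, -3, 32))
  fx <- sample_mesh_fixture(a, tube_radius_mm = 8)
  v <- fx$mesh$vertices
  for (nm in landmark_names()) {
    dmin <- min(sqrt(colSums((t(v) - a$landmarks[nm, ])^2)))
    expect_lt(dmin, 1e-9)
  }
  # snapping to the fixture leaves measurements unchanged
  snapped <- snap_to_surface(a, fx$mesh)
  m0 <- measure_anatomy(a)
  m1 <- measure_anatomy(snapped)
  expect_equal(m1$d_pv_svd, m0$d_pv_svd, tolerance = 1e-9)
  expect_equal(m1$d_pv_azygos, m0$d_pv_azygos, tolerance = 1e-9)
  expect_true(all(attr(snapped, "snap_displacement_mm") < 1e-9))

  # perturbed annotations snap back within the mesh resolution
  b <- make_anatomy(pv = c(5.3, -3, 12.1), svd = c(5, -2.8, -8.2),
                    azy = c(4.9, -3.1, 31.9), id = "T002")
  sb <- snap_to_surface(b, fx$mesh)
  mb <- measure_anatomy(sb)
  edge <- 2 * pi * 8 / 24  # circumferential edge length
  expect_lt(abs(mb$d_pv_svd - m0$d_pv_svd), edge)
  expect_lt(abs(mb$d_pv_azygos - m0$d_pv_azygos), edge)

  expect_error(sample_mesh_fixture(a, tube_radius_mm = 0), "positive")
  off_axis <- make_anatomy(pv = c(9, 2, 12), svd = c(5, -3, -8),
                           azy = c(5, -3, 32))
  expect_error(sample_mesh_fixture(off_axis, 8), "not collinear")
})

test_that("the prospective fixture is deterministic and classifies 3/3", {
  fx <- prospective_fixture()
  expect_identical(fx, prospective_fixture())
  expect_equal(nrow(fx), 6L)
  expect_identical(fx$ratio[1:3], c(0.99, 0.82, 0.88))
  expect_identical(fx$source, c(rep("reported", 3), rep("synthetic", 3)))
  pred <- classify_procedure(fx$ratio, 0.68)
  expect_identical(as.character(pred),
                   c(rep("WARDEN", 3), rep("PATCH", 3)))
})
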