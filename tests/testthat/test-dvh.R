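rand_dose_mask <- function(n = c(8, 7, 6), rx = 100) {
  d <- vox_grid(array(runif(prod(n), 0, 1.1 * rx), n), c(2, 2, 2),
                kind = "dose")
  m <- vox_grid(array(runif(prod(n)) < 0.4, n), c(2, 2, 2), kind = "mask")
  if (!any(m$values)) m$values[1] <- TRUE
  list(dose = d, mask = m)
}

test_that("cumulative DVH of uniform dose is a step function starting at 1", {
  d <- vox_grid(array(60, c(5, 5, 5)), c(2, 2, 2), kind = "dose")
  m <- vox_grid(array(TRUE, c(5, 5, 5)), c(2, 2, 2), kind = "mask")
  dvh <- cumulative_dvh(d, m, rx = 100, n_bins = 110)
  expect_equal(dvh$volume_fraction[1], 1.0)
  expect_true(all(diff(dvh$volume_fraction) <= 0))
  expect_true(all(dvh$volume_fraction[dvh$dose <= 60] == 1))
  expect_true(all(dvh$volume_fraction[dvh$dose > 60] == 0))
})

test_that("cumulative DVH equals per-voxel counting on small random grids", {
  set.seed(31)
  for (i in 1:20) {
    rm <- rand_dose_mask()
    dvh <- cumulative_dvh(rm$dose, rm$mask, rx = 100, n_bins = 50)
    dd <- rm$dose$values[rm$mask$values]
    brute <- vapply(dvh$dose, function(e) sum(dd >= e) / length(dd), 0)
    expect_equal(dvh$volume_fraction, brute)
  }
})

test_that("V95 counts voxels at or above threshold exactly", {
  n <- c(10, 10, 1)
  m <- vox_grid(array(TRUE, n), c(2, 2, 2), kind = "mask")
  d <- vox_grid(array(100, n), c(2, 2, 2), kind = "dose")
  expect_equal(v_at(d, m, rx = 100, 95), 100)
  half <- array(c(rep(100, 50), rep(0, 50)), n)
  expect_equal(v_at(vox_grid(half, c(2, 2, 2), kind = "dose"), m, 100, 95), 50)
  expect_error(v_at(d, vox_grid(array(FALSE, n), c(2, 2, 2), kind = "mask"), 100),
               class = "protonWET_empty_mask_error")
})

test_that("D-at-volume matches the sorting brute force on random masks", {
  set.seed(32)
  for (i in 1:20) {
    rm <- rand_dose_mask()
    dd <- rm$dose$values[rm$mask$values]
    for (p in c(2, 50, 95, 100)) {
      k <- ceiling(p / 100 * length(dd))
      expect_equal(d_at(rm$dose, rm$mask, 100, p),
                   100 * sort(dd, decreasing = TRUE)[k] / 100)
    }
    expect_error(d_at(rm$dose, rm$mask, 100, 0), class = "protonWET_error")
  }
})

test_that("v_at is non-increasing in threshold and d_at in volume", {
  set.seed(33)
  rm <- rand_dose_mask(c(10, 9, 8))
  v <- vapply(seq(5, 105, by = 10), function(t) v_at(rm$dose, rm$mask, 100, t), 0)
  expect_true(all(diff(v) <= 0))
  d <- vapply(seq(5, 100, by = 5), function(p) d_at(rm$dose, rm$mask, 100, p), 0)
  expect_true(all(diff(d) <= 0))
})

test_that("conformity index is isodose volume over target volume", {
  n <- c(10, 10, 2)
  dose_arr <- array(0, n); dose_arr[1:60] <- 100; dose_arr[61:120] <- 120
  d <- vox_grid(dose_arr, c(2, 2, 2), kind = "dose")
  ctv <- array(FALSE, n); ctv[1:100] <- TRUE
  m <- vox_grid(ctv, c(2, 2, 2), kind = "mask")
  expect_equal(conformity_index(d, m, rx = 100), 1.2)
  expect_equal(conformity_index(d, m, rx = 200), 0)
  exact <- vox_grid(array(ifelse(ctv, 100, 0), n), c(2, 2, 2), kind = "dose")
  expect_equal(conformity_index(exact, m, rx = 100), 1.0)
})

test_that("worst case takes per-metric extrema across scenarios", {
  mk <- function(v95, mx) structure(list(v95_pct = v95, d95_pct = v95,
                                         max_dose_pct = mx, mean_dose_pct = v95,
                                         conformity_index = 1),
                                    class = "dvh_metrics")
  wc <- worst_case_metrics(list(mk(99.1, 104), mk(98.2, 107), mk(99.5, 103)))
  expect_equal(wc$v95_pct, 98.2)
  expect_equal(wc$max_dose_pct, 107)
  single <- worst_case_metrics(list(mk(97, 101)))
  expect_equal(single$v95_pct, 97)
  expect_error(worst_case_metrics(list()), class = "protonWET_error")
})

test_that("worst-case coverage never beats nominal on scenario doses", {
  pp <- test_patient()
  cal <- default_calibration()
  sc <- scenario_doses(pp$phantom, pp$plan, cal)
  rx <- pp$plan$prescription_dose
  ms <- lapply(sc, function(d) dvh_metrics(d, pp$masks$ctv, rx))
  wc <- worst_case_metrics(ms)
  expect_lte(wc$v95_pct, ms$nominal$v95_pct)
  expect_gte(wc$max_dose_pct, ms$nominal$max_dose_pct)
})

test_that("beam-specific metrics evaluate each beam against its share of the prescription", {
  n <- c(10, 10, 2)
  m <- vox_grid(array(TRUE, n), c(2, 2, 2), kind = "mask")
  half_rx <- vox_grid(array(50, n), c(2, 2, 2), kind = "dose")
  bm <- beam_specific_metrics(list(half_rx, half_rx), m, rx = 100)
  expect_equal(bm[[1]]$v95_pct, 100)  # 50 = rx/2 exactly
  expect_error(beam_specific_metrics(list(half_rx), m, 100),
               class = "protonWET_error")
})

test_that("per-beam doses sum to the plan dose", {
  pp <- test_patient()
  cal <- default_calibration()
  total <- compute_dose(pp$phantom, pp$plan, cal)
  parts <- compute_dose(pp$phantom, pp$plan, cal, per_beam = TRUE)
  expect_equal(parts[[1]]$values + parts[[2]]$values, total$values)
})
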