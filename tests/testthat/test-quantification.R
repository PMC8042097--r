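test_that("percent positive applies ROI rules and pools correctly", {
  cells <- tibble::tibble(
    roi = rep(c("wm1", "wm2", "tiny"), c(800, 1000, 10)),
    hunu = TRUE,
    sox10 = c(rep(c(TRUE, FALSE), c(600, 200)),
              rep(c(TRUE, FALSE), c(250, 750)),
              rep(TRUE, 10))
  )
  expect_warning(out <- percent_positive(cells, sox10, denominator = hunu),
                 "tiny")
  expect_equal(attr(out, "excluded"), "tiny")
  expect_equal(out$pct[out$roi == "wm1"], 75)
  expect_equal(out$pct[out$roi == "wm2"], 25)
  pooled <- out$pct[out$roi == "pooled"]
  expect_equal(pooled, 100 * 850 / 1800)
  expect_true(pooled >= min(out$pct[out$roi != "pooled"]) &&
              pooled <= max(out$pct[out$roi != "pooled"]))

  small <- tibble::tibble(roi = "r", pos = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(percent_positive(small, pos, min_cells = 1)$pct[1], 75)
})

test_that("a planted positive fraction is estimated within the binomial band", {
  f <- simulate_cell_field(n_cells = 1000, positive_fraction = 0.4, seed = 6)
  cells <- dplyr::mutate(f$cells, pos = f$truth$positive, roi = "field")
  out <- percent_positive(cells, pos, min_cells = 100)
  expect_equal(out$pct[out$roi == "field"], 40, tolerance = 0.1)
})

test_that("percentile tiering uses the 25th/75th cuts and rescales stably", {
  set.seed(7)
  cells <- tibble::tibble(intensity = runif(5000, 0, 100))
  out <- tier_by_intensity(cells, mode = "percentile")
  thr <- attr(out, "thresholds")
  expect_equal(unname(thr["low"]), 25, tolerance = 0.1)
  expect_equal(unname(thr["high"]), 75, tolerance = 0.1)
  expect_true(thr["low"] <= thr["high"])
  scaled <- dplyr::mutate(cells, intensity = intensity * 3.7)
  expect_equal(tier_by_intensity(scaled, mode = "percentile")$tier, out$tier)
  expect_error(tier_by_intensity(cells[1:50, ], mode = "percentile"),
               "100")
})

test_that("reference tiering is background-anchored", {
  cells <- tibble::tibble(intensity = c(5, 25, 90))
  out <- tier_by_intensity(cells, mode = "reference", background = 20,
                           high_reference = seq(80, 120, length.out = 25))
  expect_equal(as.character(out$tier), c("negative", "low", "high"))
  expect_error(tier_by_intensity(cells, mode = "reference", background = 20,
                                 high_reference = c(80, 90)), "20")
  expect_error(tier_by_intensity(cells, mode = "reference",
                                 high_reference = 1:30), "background")
})

test_that("disjoint planted tier bands are recovered perfectly", {
  f <- simulate_cell_field(n_cells = 400, positive_fraction = 0.6, seed = 9)
  out <- tier_by_intensity(f$cells, mode = "reference", background = 20,
                           high_reference = f$cells$intensity[f$truth$tier == "high"])
  expect_identical(as.character(out$tier), as.character(f$truth$tier))
})

test_that("axon contact uses the nucleus edge with a strict threshold", {
  path <- tibble::tibble(path_id = "p1", x = c(0, 10), y = c(0, 0))
  cells <- tibble::tibble(
    x = c(5, 5, 5), y = c(4.5, 4.49, 0), nucleus_radius = 3
  )
  out <- axon_contact(cells, path)
  # edge at exactly 1.5 um: no contact (strict); just under: contact;
  # centre on the axon: contact
  expect_equal(out$contact, c(FALSE, TRUE, TRUE))
  expect_equal(out$axon_distance, c(1.5, 1.49, -3))

  expect_warning(none <- axon_contact(cells, path[0, ]), "no axon paths")
  expect_false(any(none$contact))
})

test_that("myelin disruption needs axons and a deep intensity drop", {
  rois <- tibble::tibble(
    mean_grey = c(100, 20, 20, 24.9),
    max_grey = c(100, 100, 100, 100),
    has_axons = c(TRUE, TRUE, FALSE, TRUE)
  )
  out <- myelin_disruption(rois, contralateral_normalised = 1)
  expect_equal(out$normalised_intensity, c(1, 0.2, 0.2, 0.249))
  expect_equal(out$disrupted, c(FALSE, TRUE, FALSE, TRUE))
  # no contralateral reference: intensity still returned, call undefined
  und <- myelin_disruption(rois)
  expect_true(all(is.na(und$disrupted)))
  expect_error(myelin_disruption(dplyr::mutate(rois, max_grey = 0)), "max_grey")
})

test_that("invasion index and migrated distances follow the geometry", {
  bulk <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  # tumour positions spanning a 2x2 square: hull area 4, bulk perimeter 4
  cells <- tibble::tibble(x = c(0, 2, 2, 0, 1), y = c(0, 0, 2, 2, 1))
  inv <- invasion_metrics(cells, bulk)
  expect_equal(inv$invasion_index, 1)
  expect_equal(inv$bulk_perimeter, 4)

  inside <- tibble::tibble(x = c(0.2, 0.5, 0.8), y = c(0.2, 0.5, 0.8))
  expect_equal(invasion_metrics(inside, bulk)$cells$migrated_distance,
               c(0, 0, 0))

  far <- tibble::tibble(x = 101, y = 0.5)
  expect_equal(invasion_metrics(far, bulk)$cells$migrated_distance, 100)
  few <- invasion_metrics(far, bulk)
  expect_true(is.na(few$invasion_index))
  # externally measured area overrides the hull
  expect_equal(invasion_metrics(far, bulk, occupied_area = 8)$invasion_index, 2)
})

test_that("track metrics capture path, displacement, straightness and speed", {
  straight <- tibble::tibble(cell_id = "c1", t = 0:3,
                             x = c(0, 5, 10, 15), y = 0)
  out <- track_metrics(straight)
  expect_equal(out$path_length, 15)
  expect_equal(out$net_displacement, 15)
  expect_equal(out$straightness, 1)
  expect_equal(out$mean_speed, 5)

  loop <- tibble::tibble(cell_id = "c2", t = 0:4,
                         x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  lout <- track_metrics(loop)
  expect_equal(lout$net_displacement, 0)
  expect_equal(lout$straightness, 0)

  set.seed(13)
  walks <- purrr::map_dfr(1:20, function(i) {
    tibble::tibble(cell_id = paste0("w", i), t = 0:30,
                   x = cumsum(c(0, rnorm(30))), y = cumsum(c(0, rnorm(30))))
  })
  wout <- track_metrics(walks)
  expect_true(all(wout$path_length >= wout$net_displacement))
  expect_true(all(wout$straightness >= 0 & wout$straightness <= 1))

  dup <- tibble::tibble(cell_id = "c3", t = c(0, 1, 1), x = 1:3, y = 1:3)
  expect_error(track_metrics(dup), "duplicate timestamps")
})
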