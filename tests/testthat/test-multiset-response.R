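test_that("criterion scale and slope follow the BLUP/BLUE relations", {
  blue <- derive_scale_and_slope(set_params("A", 0.5, 0, 1, "BLUE", 0.36))
  expect_equal(blue$sigma_sc, 1 / 0.6, tolerance = 1e-12)
  expect_equal(blue$b, 0.36)
  blup <- derive_scale_and_slope(set_params("A", 0.5, 0, 1, "BLUP", 0.9))
  expect_equal(blup$sigma_sc, 0.9)
  expect_equal(blup$b, 1.0)
  # perfect accuracy: BLUE with h2 = 1 coincides with BLUP with rho = 1
  b1 <- derive_scale_and_slope(set_params("A", 0.5, 1, 2, "BLUE", 1))
  b2 <- derive_scale_and_slope(set_params("A", 0.5, 1, 2, "BLUP", 1))
  expect_equal(b1, b2)
  expect_error(set_params("A", 0.5, 0, 1, "BLUE", 0), "\\(0, 1\\]")
  expect_error(set_params("A", 0.5, 0, 1, "BLUP", 1.2), "\\(0, 1\\]")
  expect_error(set_params("A", 0.5, 0, -1, "BLUP", 0.5), "positive")
})

test_that("scenario validation rejects degenerate proportions", {
  s1 <- set_params("A", 0.6, 0, 1, "BLUP", 0.5)
  s2 <- set_params("B", 0.3, 0, 1, "BLUP", 0.5)
  expect_error(selection_scenario(list(s1, s2), 0.1), "sum to 1")
  expect_error(set_params("A", 1, 0, 1, "BLUP", 0.5), "within \\(0, 1\\)")
  expect_error(selection_scenario(list(s1), 0.1), "sum to 1")
  single <- selection_scenario(set_params("A", 1 - 1e-12, 0, 1, "BLUP", 0.5),
                               0.1)
  expect_s3_class(single, "selection_scenario")
})

test_that("total selected proportion is the pi-weighted tail mixture", {
  # identical sets collapse to the single-set proportion
  twin <- selection_scenario(
    list(set_params("A", 0.3, 1, 1, "BLUP", 0.7),
         set_params("B", 0.7, 1, 1, "BLUP", 0.7)), 0.2)
  t <- 1.5
  expect_equal(total_selected_proportion(c(t, t), twin),
               upper_tail_proportion((t - 1) / 0.7))
  # the worked example: the printed common threshold 1.77 spends the 10%
  # budget (to the precision the threshold is printed at)
  expect_equal(total_selected_proportion(c(1.77, 1.77), blue_example()),
               0.10, tolerance = 5e-3)
  expect_error(total_selected_proportion(1.77, blue_example()),
               "one per set")
})

test_that("post-selection composition matches stated proportions", {
  # mild selection on a small inferior set crowds out the superior set
  a <- c(0.45, 0.0125); pi <- c(0.2, 0.8)
  ex <- extreme_example()
  gam <- post_selection_composition(ex$thresholds, ex$scenario)
  expect_equal(unname(gam[1]), 0.90, tolerance = 1e-10)
  expect_equal(sum(gam), 1)
  expect_equal(unname(gam), a * pi / sum(a * pi), tolerance = 1e-9)
  # equal sets, equal thresholds: composition equals initial proportions
  twin <- selection_scenario(
    list(set_params("A", 0.3, 0, 1, "BLUE", 0.5),
         set_params("B", 0.7, 0, 1, "BLUE", 0.5)), 0.2)
  expect_equal(unname(post_selection_composition(c(1, 1), twin)),
               c(0.3, 0.7), tolerance = 1e-12)
  # worked example at the common threshold
  gam_i <- post_selection_composition(c(1.77, 1.77), blue_example())
  expect_equal(round(unname(gam_i[1]), 2), 0.72)
})

test_that("within-set response is the classical breeder's equation", {
  p1 <- set_params("P1", 0.5, 0, 1, "BLUE", 0.36)
  t_i <- solve_identical_threshold(blue_example())$thresholds[1]
  expect_equal(round(within_set_response(t_i, p1), 2), 0.94)
  p2_blup <- set_params("P2", 0.5, 0, 1, "BLUP", 0.9)
  t_b <- solve_identical_threshold(blup_example())$thresholds[1]
  expect_equal(round(within_set_response(t_b, p2_blup), 2), 1.42)
  # no selection, no response
  expect_lt(within_set_response(-30, p1), 1e-8)
  # agreement with direct construction b * sigma * i(alpha)
  t <- 0.83
  ss <- derive_scale_and_slope(p1)
  a <- upper_tail_proportion((t - 0) / ss$sigma_sc)
  expect_equal(within_set_response(t, p1),
               ss$b * ss$sigma_sc * selection_intensity(a))
})

test_that("total response reproduces the worked and extreme examples", {
  res <- total_response(c(1.77, 1.77), blue_example())
  expect_equal(round(res$deltaG_tot, 2), 1.19)
  expect_equal(res$alpha_tot, 0.10, tolerance = 5e-3)
  ex <- extreme_example()
  res_ex <- total_response(ex$thresholds, ex$scenario)
  expect_equal(round(res_ex$deltaG_tot, 2), -0.70)
  # K = 1 reduces exactly to the within-set breeder's equation
  one <- selection_scenario(
    set_params("only", 1 - 1e-12, 0.4, 1.3, "BLUE", 0.6), 0.2)
  t <- 1.1
  expect_equal(total_response(t, one)$deltaG_tot,
               within_set_response(t, one$sets[[1]]), tolerance = 1e-10)
})

test_that("total response is invariant under set relabeling", {
  withr::local_seed(421)
  for (rep in 1:10) {
    sc <- random_scenario(K = 3, criterion = "BLUE", mixed = TRUE)
    thr <- vapply(sc$sets, function(s) {
      ss <- derive_scale_and_slope(s)
      threshold_for_proportion(stats::runif(1, 0.05, 0.6), s$mu, ss$sigma_sc)
    }, numeric(1))
    perm <- sample(3)
    sc_p <- selection_scenario(sc$sets[perm], sc$alpha_T)
    r1 <- total_response(thr, sc)
    r2 <- total_response(thr[perm], sc_p)
    expect_equal(r2$deltaG_tot, r1$deltaG_tot, tolerance = 1e-12)
    expect_equal(r2$alpha_tot, r1$alpha_tot, tolerance = 1e-12)
    expect_equal(sum(r1$sets$gamma), 1)
  }
})

test_that("single-set limit recovers the closed form as pi_1 -> 1", {
  big <- set_params("big", 1 - 1e-9, 0.2, 1.1, "BLUE", 0.49)
  small <- set_params("tiny", 1e-9, -3, 0.5, "BLUE", 0.25)
  sc <- selection_scenario(list(big, small), 0.15)
  t <- c(1.4, 1.4)
  expect_equal(total_response(t, sc)$deltaG_tot,
               within_set_response(1.4, big) +
                 big$mu * 0,  # baseline shift vanishes in the limit
               tolerance = 1e-6)
})

test_that("the BLUP closed form equals the general formula", {
  # worked example value
  expect_equal(round(blup_total_response_closed_form(0.96, blup_example()), 2),
               1.36)
  # random two-set BLUP scenarios: closed form == general expression
  withr::local_seed(99)
  for (rep in 1:25) {
    sc <- random_scenario(K = 2, criterion = "BLUP")
    t <- solve_identical_threshold(sc)$thresholds[1]
    expect_equal(blup_total_response_closed_form(t, sc),
                 total_response(rep(t, 2), sc)$deltaG_tot,
                 tolerance = 1e-10)
  }
  expect_error(blup_total_response_closed_form(1, blue_example()),
               "all-BLUP")
})

test_that("scenario CSV round-trips and rejects malformed tables", {
  sc <- blue_example()
  path <- withr::local_tempfile(fileext = ".csv")
  write_scenario_csv(sc, path)
  back <- read_scenario_csv(path, alpha_T = 0.10)
  expect_equal(as.data.frame(back), as.data.frame(sc))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("label,pi,mu\nA,0.5,0", bad)
  expect_error(read_scenario_csv(bad, 0.1), "missing column")
  # bundled example scenario loads and reproduces the worked numbers
  shipped <- system.file("extdata", "blue_example.csv", package = "truncsel")
  expect_equal(as.data.frame(read_scenario_csv(shipped, 0.10)),
               as.data.frame(sc))
})
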