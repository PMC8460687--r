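test_that("local PCC matches the textbook double-loop oracle", {
  set.seed(7)
  for (rep in 1:6) {
    a <- matrix(runif(9 * 9), 9, 9)
    b <- matrix(runif(9 * 9), 9, 9)
    got <- local_pcc(a, b, 5)
    want <- oracle_local_pcc(a, b, 5)
    expect_lt(max(abs(got$pcc - want), na.rm = TRUE), 1e-12)
    expect_identical(is.na(got$pcc), is.na(want))
  }
  # identity and anti-correlation
  set.seed(8)
  a <- matrix(runif(64), 8, 8)
  expect_true(all(abs(local_pcc(a, a, 3)$pcc - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(local_pcc(a, 1 - a, 3)$pcc + 1) < 1e-12, na.rm = TRUE))
})

test_that("local PCC window side is the largest odd number, at least 3", {
  set.seed(9)
  a <- matrix(runif(81), 9, 9); b <- matrix(runif(81), 9, 9)
  expect_equal(local_pcc(a, b, 4)$pcc, oracle_local_pcc(a, b, 3),
               tolerance = 1e-12)
  expect_equal(local_pcc(a, b, 1)$pcc, oracle_local_pcc(a, b, 3),
               tolerance = 1e-12)
  expect_equal(local_pcc(a, b, 7)$pcc, oracle_local_pcc(a, b, 7),
               tolerance = 1e-12)
})

test_that("flat windows are classified as agreement, disagreement or void", {
  a <- matrix(0, 9, 9); b <- matrix(0, 9, 9)
  a[, 1:4] <- 1                       # left half structure in a only
  b[, 1:4] <- 1
  both <- local_pcc(a, b, 3)
  expect_true(all(both$agree_flat[, 1:3]))     # identical structure content
  expect_false(any(both$no_evidence[, 1:3]))
  expect_true(all(both$no_evidence[, 6:9]))    # empty in both: vacuous
  expect_false(any(both$agree_flat[, 6:9]))

  b0 <- matrix(0, 9, 9)
  onesided <- local_pcc(a, b0, 3)
  expect_true(all(onesided$undefined[, 1:3]))
  expect_false(any(onesided$agree_flat[, 1:3]))  # flat at different levels
})

test_that("confidence score saturates at the 0.85 full-confidence level", {
  expect_equal(confidence_score(0.85, 0.85), 1.0)
  expect_equal(confidence_score(0.425, 0.425), 0.5)
  expect_equal(confidence_score(-0.3, 1.0), 0.5)   # negative term clamps
  expect_equal(confidence_score(1, 1), 1.0)
  expect_equal(confidence_score(-1, -1), 0.0)
  expect_equal(confidence_score(NA, 0.85), 1.0)    # void term dropped
  expect_true(is.na(confidence_score(NA, NA)))
  grid <- confidence_score(matrix(seq(-1, 1, length.out = 25), 5, 5),
                           matrix(seq(1, -1, length.out = 25), 5, 5))
  expect_true(all(grid >= 0 & grid <= 1))
})

test_that("overlay maps follow the yellow/magenta/cyan convention", {
  m <- matrix(FALSE, 6, 6); m[2:4, 2:4] <- TRUE
  same <- overlay_map(m, m)
  expect_true(all(same[, , 1][m] == 1 & same[, , 2][m] == 1 &
                    same[, , 3][m] == 0))          # yellow
  disj <- overlay_map(m, !m)
  expect_true(all(disj[, , 3] == 1))               # no yellow anywhere
  # swap symmetry: magenta and cyan exchange exactly
  set.seed(10)
  a <- matrix(runif(100) > 0.5, 10, 10)
  b <- matrix(runif(100) > 0.5, 10, 10)
  ab <- overlay_map(a, b); ba <- overlay_map(b, a)
  expect_identical(ab[, , 1], ba[, , 2])
  expect_identical(ab[, , 2], ba[, , 1])
  expect_identical(ab[, , 3], ba[, , 3])
})

test_that("confidence map colours follow score and brightness", {
  line <- matrix(0, 5, 9); line[3, ] <- 1
  cyan <- confidence_map(line, matrix(1, 5, 9))
  expect_true(all(cyan[3, , 1] == 0 & cyan[3, , 2] == 1 & cyan[3, , 3] == 1))
  red <- confidence_map(line, matrix(0, 5, 9))
  expect_true(all(red[3, , 1] == 1 & red[3, , 2] == 0 & red[3, , 3] == 0))
  expect_true(all(red[1, , ] == 0))   # zero combined intensity stays black
})

test_that("global metrics match the whole-frame correlation oracle", {
  set.seed(11)
  m <- matrix(runif(100) > 0.5, 10, 10)
  g <- global_metrics(m, m, m * 1.0, m * 1.0)
  expect_equal(g$pcc_sharp, 1.0)
  expect_equal(g$pcc_str, 1.0)
  expect_equal(global_metrics(m, !m, m * 1.0, 1 - m)$pcc_sharp, -1.0)
  expect_true(is.na(global_metrics(m, matrix(TRUE, 10, 10), m * 1.0,
                                   m * 1.0)$pcc_sharp))
  # independent dense random masks decorrelate
  set.seed(12)
  a <- matrix(runif(1e4) > 0.5, 100, 100)
  b <- matrix(runif(1e4) > 0.5, 100, 100)
  expect_lt(abs(global_metrics(a, b, a * 1.0, b * 1.0)$pcc_sharp), 0.05)
  # oracle equivalence on structured grids
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  expect_lt(abs(global_metrics(x > 0.5, y > 0.5, x, y)$pcc_str -
                  oracle_global_pcc(x, y)), 1e-12)
})

test_that("artefact scale map records the first 90% crossing", {
  stack <- list(matrix(0.2, 2, 2), matrix(0.5, 2, 2),
                matrix(0.95, 2, 2), matrix(0.99, 2, 2))
  stack[[3]][2, 2] <- 0.1; stack[[4]][2, 2] <- 0.1   # never confident
  stack[[1]][1, 1] <- 1                              # confident at once
  am <- artefact_scale_map(stack, matrix(1, 2, 2))
  expect_equal(am$scale[1, 1], 1L)
  expect_equal(am$scale[1, 2], 3L)
  expect_true(is.na(am$scale[2, 2]))
  expect_error(artefact_scale_map(list(), matrix(1, 2, 2)), "empty")
  rgb <- render_artefact_map(am)
  expect_equal(dim(rgb), c(2L, 2L, 3L))
  # sentinel pixel renders grey: equal channels
  expect_true(length(unique(rgb[2, 2, ])) == 1L)
})

test_that("run_hawkman on identical images gives full confidence", {
  img <- crossing_image(64, sigma_px = 2)
  res <- run_hawkman(img, img, threshold_params(psf_scale_no = 8),
                     max_scale_no = 6)
  expect_s3_class(res, "hawkman")
  for (sc in res$scales) {
    on_structure <- sc$sharp_test
    expect_true(all(abs(sc$s_conf[on_structure] - 1) < 1e-12))
    expect_equal(sc$pcc_sharp_global, 1.0)
    expect_equal(sc$pcc_str_global, 1.0)
  }
  expect_true(all(res$artefact$scale[res$scales[[1]]$sharp_test] == 1L))
})

test_that("run_hawkman is symmetric in its two inputs", {
  set.seed(13)
  a <- recon_image(matrix(rpois(32 * 32, 0.5), 32, 32) * 1.0, 10, "a")
  b <- recon_image(matrix(rpois(32 * 32, 0.5), 32, 32) * 1.0, 10, "b")
  p <- threshold_params(psf_scale_no = 6)
  r1 <- run_hawkman(a, b, p, max_scale_no = 4)
  r2 <- run_hawkman(b, a, p, max_scale_no = 4)
  for (s in 1:4) {
    expect_identical(r1$scales[[s]]$s_conf, r2$scales[[s]]$s_conf)
    expect_identical(r1$scales[[s]]$pcc_sharp_global,
                     r2$scales[[s]]$pcc_sharp_global)
    expect_identical(r1$scales[[s]]$pcc_str_global,
                     r2$scales[[s]]$pcc_str_global)
  }
  expect_error(run_hawkman(a, recon_image(matrix(1, 16, 16), 10)),
               "differ in size")
})

test_that("summary and print methods expose the metrics table", {
  img <- crossing_image(48, sigma_px = 2)
  res <- run_hawkman(img, img, threshold_params(psf_scale_no = 5),
                     max_scale_no = 3)
  expect_output(print(res), "global PCC")
  s <- summary(res)
  expect_s3_class(s, "summary.hawkman")
  expect_output(print(s), "scale_no")
  expect_equal(nrow(s$metrics), 3L)
})
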