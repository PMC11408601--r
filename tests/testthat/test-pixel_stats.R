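test_that("pixel regression: exact fits, degenerate designs, oracle equality", {
  x <- matrix(seq_len(100), 10)
  y <- 2 * x
  fit <- suppressWarnings(pixel_regression(x, y))  # lm flags the exact fit
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 100)
  yc <- matrix(5, 10, 10)
  fit0 <- pixel_regression(x, yc)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r_squared, 0)
  expect_error(pixel_regression(matrix(3, 10, 10), y), "degenerate")
  m <- matrix(FALSE, 10, 10); m[1, 1:2] <- TRUE
  expect_error(pixel_regression(x, y, m), "fewer than 3")
  # equality with the closed-form sum oracle on random instances
  for (s in 1:10) {
    set.seed(s)
    gx <- matrix(rnorm(400, 100, 30), 20)
    gy <- matrix(0.7 * gx + rnorm(400, 0, 25), 20)
    f <- pixel_regression(gx, gy)
    o <- ols_sums(as.vector(gx), as.vector(gy))
    expect_equal(f$slope, o$slope)
    expect_equal(f$intercept, o$intercept)
    expect_equal(f$r_squared, o$r_squared)
  }
})

test_that("per-cell slopes straddle zero on flat scenes with Poisson noise", {
  slopes <- r2 <- numeric(12)
  for (s in 1:12) {
    tru <- regression_scene(slope = 0, intercept = 100, seed = s)
    st <- sample_counts(tru, seed = 5000 + s)
    y <- enrichment_image(st, rds[["15N_RNA"]], 20)
    m <- tru$compartment_map == tru$compartments[["nucleoplasm"]]
    f <- pixel_regression(tru$expected_enrichment[["13C_DNA"]], y, m,
                          cell_id = sprintf("cell_%d", s))
    slopes[s] <- f$slope; r2[s] <- f$r_squared
  }
  expect_gt(sum(slopes > 0), 0)
  expect_gt(sum(slopes < 0), 0)
  expect_true(all(r2 < 0.1))
  expect_lt(median(abs(slopes)), 0.2)
})

test_that("dispersion: hand-computed values and MAD robustness to outliers", {
  d <- dispersion(c(1, 2, 3, 4, 5))
  expect_equal(d$median, 3)
  expect_equal(d$mad, 1)  # raw MAD, no consistency constant
  d2 <- dispersion(c(1, 2, 3, 4, 100))
  expect_equal(d2$mad, 1)
  expect_gt(d2$sd, 40)
  d3 <- dispersion(c(2, 2, 2))
  expect_equal(d3$mad, 0)
  expect_equal(d3$cov, 0)
  expect_warning(dd <- dispersion(c(-2, 0, 2)), "cov undefined")
  expect_true(is.na(dd$cov))
  # breakdown: replacing up to 49% of values on one side leaves MAD bounded
  base <- 1:100
  contaminated <- c(base[1:51], rep(1e6, 49))
  expect_equal(dispersion(contaminated)$median, 50.5)
  expect_lte(dispersion(contaminated)$mad, 50)
  # cov uses the sample (n-1) standard deviation
  expect_equal(dispersion(c(1, 2, 3))$cov, sd(c(1, 2, 3)) / 2)
})

test_that("top-percentile subset uses nearest-rank with ties included", {
  g <- matrix(1:100, 10)
  m <- matrix(TRUE, 10, 10)
  res <- top_percentile_subset(g, m, 5)
  expect_equal(sort(g[res$roi$mask]), 96:100)
  expect_equal(res$cutoff, 96)
  # ties at the cutoff are all included; subset may exceed pct*n
  gt <- matrix(c(1:95, rep(96, 5)), 10)
  rt <- top_percentile_subset(gt, m, 5)
  expect_equal(rt$n_subset, 5)
  gt2 <- matrix(c(1:90, rep(91, 10)), 10)
  rt2 <- top_percentile_subset(gt2, m, 5)
  expect_equal(rt2$n_subset, 10)
  expect_gte(rt2$n_subset, ceiling(5 * 100 / 100))
  expect_error(top_percentile_subset(g, m, 0), "pct")
  expect_error(top_percentile_subset(g, m, 100), "pct")
})

test_that("top-density pixels report the companion tracer against the 37 line", {
  # densest-DNA compartment carries RNA multiplier 0.5
  enr <- uniform_enrichment(0)
  enr["13C_DNA", ] <- c(0, 0, 0.5, 3.0, 0.5, 0)
  enr["15N_RNA", ] <- c(0, 0, 0.05, 0.5, 0.05, 0)
  spec <- scene_spec(image_shape = c(64L, 64L),
                     nucleus = list(center = c(32.5, 32.5),
                                    semi_axes = c(24, 19), angle = 0),
                     nucleoli = list(), lamina_width = 2,
                     chromatin = list(base = 1, n_foci = 5, amplitude = 0,
                                      radius = 3, correlation_length = 2,
                                      field_sd = 0),
                     enrichment = enr, count_budget = 3000, seed = 2)
  truth <- build_scene(spec)
  st <- sample_counts(truth, 2)
  dna <- enrichment_image(st, rds[["13C_DNA"]], 20)
  nuc <- truth_roi(truth, "nucleus")
  res <- top_percentile_subset(dna, nuc, 5, stack = st,
                               companion_rd = rds[["15N_RNA"]])
  expect_equal(res$background_scaled, 37)
  # subset is dominated by the dense foci, so companion enrichment ~ 50%
  expect_lt(abs(res$companion$enrichment - 50), 10)
  expect_gt(res$companion$enrichment, 0)  # above the background line
})

test_that("pulse-chase table aggregates per timepoint and compartment", {
  one <- data.frame(cell_id = "c1", timepoint = 15, compartment = "nucleus",
                    enrichment = 42)
  t1 <- pulse_chase_table(one)
  expect_equal(t1$mean, 42)
  expect_true(is.na(t1$sd))
  # simulated pulse series with rising multipliers recovers monotone means
  mults <- c(`15` = 0.3, `60` = 1.0, `120` = 2.0)
  recs <- list()
  for (tp in names(mults)) for (cell in 1:4) {
    enr <- default_enrichment()
    enr["15N_RNA", ] <- c(0, 0.1, mults[[tp]], mults[[tp]], mults[[tp]], mults[[tp]])
    truth <- build_scene(flat_scene_spec(enrichment = enr,
                                         seed = cell))
    st <- sample_counts(truth, cell + 100 * as.integer(tp))
    p <- pooled_roi_ratio(st, truth_roi(truth, "nucleus"), rds[["15N_RNA"]])
    recs[[length(recs) + 1L]] <- data.frame(
      cell_id = sprintf("c%d", cell), timepoint = as.integer(tp),
      compartment = "nucleus", enrichment = p$enrichment)
  }
  tab <- pulse_chase_table(do.call(rbind, recs))
  tab <- tab[order(tab$timepoint), ]
  expect_equal(tab$n_cells, rep(4, 3))
  expect_true(all(diff(tab$mean) > 0))
  expect_equal(tab$mean, 100 * unname(mults), tolerance = 0.1)
})

test_that("condition contrast reports percent change against the reference", {
  g <- list(ctrl = c(95, 100, 105), stim = c(145, 150, 155))
  cc <- condition_contrast(g, "ctrl")
  expect_equal(cc$pct_change_vs_reference, c(0, 50))
  expect_true(cc$ci_lower[1] < 100 & cc$ci_upper[1] > 100)
  same <- condition_contrast(list(a = c(1, 2), b = c(1, 2)), "a")
  expect_equal(same$pct_change_vs_reference[2], 0)
  expect_error(condition_contrast(g, "nope"), "unknown reference")
  expect_error(condition_contrast(list(a = 1), "a"), "at least 2")
})
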