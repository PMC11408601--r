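test_that("multiplier 0 everywhere gives natural abundance everywhere", {
  truth <- build_scene(flat_scene_spec(enrichment = uniform_enrichment(0)))
  for (tr in c("15N_RNA", "13C_DNA", "2H_DNA"))
    expect_true(all(truth$expected_enrichment[[tr]] == 0))
  e <- enrichment_image(truth$expected_counts, rds[["15N_RNA"]], 1)
  expect_equal(max(abs(e$values)), 0, tolerance = 1e-10)
})

test_that("compartment multipliers force the expected enrichments and folds", {
  enr <- default_enrichment()
  enr["15N_RNA", ] <- c(0, 0, 1.0, 1.0, 0, 3.0)
  enr["13C_DNA", ] <- c(0, 0, 1.0, 1.0, 2.0, 0)
  truth <- build_scene(flat_scene_spec(
    nucleoli = list(list(center = c(28, 28), radius = 6)), enrichment = enr))
  cm <- truth$compartment_map; cp <- truth$compartments
  rna <- truth$expected_enrichment[["15N_RNA"]]
  dna <- truth$expected_enrichment[["13C_DNA"]]
  expect_equal(unique(rna[cm == cp[["nucleolus"]]]), 300)
  expect_equal(unique(rna[cm == cp[["nucleoplasm"]]]), 100)
  expect_equal(unique(rna[cm == cp[["lamina"]]]), 0)
  expect_equal(unique(dna[cm == cp[["lamina"]]]), 200)
  # threefold nucleolar excess over nucleoplasm in raw-ratio excess terms:
  # multipliers 3.0 vs 1.0 give (R_nl - R0)/(R_np - R0) = 3
  r_nl <- unique(truth$expected_counts[["12C15N"]][cm == cp[["nucleolus"]]] /
                 truth$expected_counts[["12C14N"]][cm == cp[["nucleolus"]]])
  r_np <- unique(truth$expected_counts[["12C15N"]][cm == cp[["nucleoplasm"]]] /
                 truth$expected_counts[["12C14N"]][cm == cp[["nucleoplasm"]]])
  R0 <- rds[["15N_RNA"]]$R0
  expect_equal((r_nl - R0) / (r_np - R0), 3, tolerance = 1e-12)
  expect_equal(unique(r_nl / R0), 4, tolerance = 1e-12)  # ratio itself is 4x R0
})

test_that("geometry violations are rejected", {
  expect_error(flat_scene_spec(nucleoli = list(list(center = c(4, 4),
                                                    radius = 5))),
               "geometry error")
  expect_error(scene_spec(nucleus = list(center = c(64, 64),
                                         semi_axes = c(10, 8), angle = 0),
                          nucleoli = list(), lamina_width = 9),
               "geometry error")
  expect_error(flat_scene_spec(enrichment = uniform_enrichment(-1)),
               ">= 0")
})

test_that("compartments partition every pixel exactly once", {
  for (seed in 1:3) {
    truth <- build_scene(scene_spec(seed = seed))
    cm <- truth$compartment_map
    expect_true(all(cm %in% truth$compartments))
    areas <- table(factor(cm, levels = truth$compartments))
    expect_equal(sum(areas), prod(dim(cm)))
    # nucleoli and lamina inside the nucleus, foci inside the inner nucleus
    expect_equal(sum(cm == truth$compartments[["nucleolus"]] |
                     cm == truth$compartments[["lamina"]] |
                     cm == truth$compartments[["chromatin_focus"]] |
                     cm == truth$compartments[["nucleoplasm"]]),
                 sum(truth_roi(truth, "nucleus")$mask))
  }
})

test_that("simulator/analyzer closure holds on expected counts for all ratio tracers", {
  truth <- build_scene(scene_spec(seed = 5))  # textured scene
  for (tr in c("15N_RNA", "13C_DNA", "2H_DNA")) {
    e <- enrichment_image(truth$expected_counts, rds[[tr]], 1)
    expect_true(all(e$valid))
    rel <- abs(e$values - truth$expected_enrichment[[tr]]) /
      pmax(abs(truth$expected_enrichment[[tr]]), 1)
    expect_lt(max(rel), 1e-9)
  }
})

test_that("Poisson sampling: determinism, zero means, and mean recovery", {
  truth <- build_scene(flat_scene_spec())
  s1a <- sample_counts(truth, 1); s1b <- sample_counts(truth, 1)
  s2 <- sample_counts(truth, 2)
  expect_identical(s1a$channels, s1b$channels)
  expect_false(identical(s1a$channels, s2$channels))
  # expected count 0 -> sampled 0 always
  zt <- structure(list(expected_counts = list(z = matrix(0, 20, 20)),
                       pixel_size = 100), class = "scene_truth")
  expect_true(all(sample_counts(zt, 1)$channels$z == 0))
  # uniform expected count 100 over 1e4 px: sample mean within 0.3 of 100
  ut <- structure(list(expected_counts = list(u = matrix(100, 100, 100)),
                       pixel_size = 100), class = "scene_truth")
  for (s in 1:5)
    expect_lt(abs(mean(sample_counts(ut, s)$channels$u) - 100), 0.3)
})

test_that("sampled counts have Poisson variance/mean near 1 at budget >= 50", {
  ut <- structure(list(expected_counts = list(u = matrix(80, 50, 50)),
                       pixel_size = 100), class = "scene_truth")
  vm <- vapply(1:20, function(s) {
    v <- as.vector(sample_counts(ut, s)$channels$u)
    stats::var(v) / mean(v)
  }, numeric(1))
  expect_true(all(vm > 0.9 & vm < 1.1))
})

test_that("scene truth summary aggregates areas and enrichments", {
  enr <- uniform_enrichment(0)
  enr["15N_RNA", "nucleolus"] <- 2.5
  truth <- build_scene(flat_scene_spec(
    nucleoli = list(list(center = c(30, 30), radius = 10)), enrichment = enr))
  sm <- scene_truth_summary(truth)
  expect_equal(sum(sm$area_px), prod(dim(truth$compartment_map)))
  nl <- sm[sm$compartment == "nucleolus", ]
  # rasterized disc area within 5% of pi r^2
  expect_lt(abs(nl$area_px - pi * 100) / (pi * 100), 0.05)
  expect_equal(nl$enrichment_15N_RNA, 250)
  expect_equal(nl$area_um2, nl$area_px * 0.01)
  # single-compartment degenerate grid
  one <- structure(list(compartment_map = matrix(0L, 4, 4),
                        compartments = c(background = 0L),
                        expected_enrichment = list(t = matrix(0, 4, 4)),
                        pixel_size = 100), class = "scene_truth")
  expect_equal(scene_truth_summary(one)$area_px, 16)
})

test_that("regression scene encodes the prescribed DNA-RNA slope exactly", {
  tru <- regression_scene(slope = -0.5, intercept = 200, seed = 3)
  m <- tru$compartment_map == tru$compartments[["nucleoplasm"]]
  x <- tru$expected_enrichment[["13C_DNA"]][m]
  y <- tru$expected_enrichment[["15N_RNA"]][m]
  fit <- ols_sums(x, y)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 200, tolerance = 1e-9)
  expect_equal(range(x), c(50, 150), tolerance = 1e-9)
  expect_error(regression_scene(slope = -3, intercept = 10), "negative RNA")
})
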