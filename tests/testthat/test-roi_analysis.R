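test_that("P-threshold segmentation recovers the true nucleus (IoU >= 0.90)", {
  truth <- build_scene(scene_spec(seed = 2))
  stack <- sample_counts(truth, 2)
  nuc <- segment_nucleus(stack, "P_threshold")
  tn <- truth_roi(truth, "nucleus")
  iou <- sum(nuc$mask & tn$mask) / sum(nuc$mask | tn$mask)
  expect_gte(iou, 0.90)
  expect_equal(nuc$kind, "nucleus")
  # invariance to positive rescaling of the channel (data-relative threshold)
  st2 <- stack
  st2$channels[["31P"]] <- stack$channels[["31P"]] * 4
  expect_equal(segment_nucleus(st2, "P_threshold")$mask, nuc$mask)
})

test_that("blank channel and undersized components are segmentation failures", {
  st <- mass_stack(list(`31P` = matrix(0L, 32, 32)), pixel_size = 100)
  expect_error(segment_nucleus(st, "P_threshold"), "segmentation failure")
  tiny <- matrix(0, 32, 32); tiny[16, 16] <- 100
  st2 <- mass_stack(list(`31P` = tiny), pixel_size = 100)
  expect_error(segment_nucleus(st2, "P_threshold"), "segmentation failure")
})

test_that("two nuclei: largest returned, multi-instance variant returns both disjoint", {
  p <- matrix(1, 72, 72)
  big <- ellipse_px(72, c(20, 22), c(13, 11))
  small <- ellipse_px(72, c(52, 50), c(9, 8))
  p[big] <- 300; p[small] <- 300
  st <- mass_stack(list(`31P` = p), pixel_size = 100)
  one <- segment_nucleus(st, "P_threshold")
  expect_gt(sum(one$mask & big) / sum(big), 0.8)
  both <- segment_nuclei(st, "P_threshold")
  expect_length(both, 2L)
  expect_equal(sum(both[[1]]$mask & both[[2]]$mask), 0L)
  expect_gte(sum(both[[1]]$mask), sum(both[[2]]$mask))
})

test_that("line profiles: constant field, step edge, and laminar lag", {
  const <- matrix(42, 40, 40)
  lp <- line_profile(list(c = const), rbind(c(20, 3), c(20, 38)), width = 3)
  expect_true(all(abs(lp$samples$c - 42) < 1e-12))
  expect_error(line_profile(list(c = const), rbind(c(20, -3), c(20, 38))),
               "exits the image")
  # vertical step 0 | 200 at col 20, crossed horizontally
  step <- matrix(0, 40, 40); step[, 20:40] <- 200
  w <- 3
  lp2 <- line_profile(list(s = step), rbind(c(20, 5), c(20, 36)), width = w)
  v <- lp2$samples$s
  lo <- max(which(v <= 10)); hi <- min(which(v >= 190))
  expect_lte(hi - lo, w + 2)
  # lamina scene: DNA peaks before RNA rises moving inward
  enr <- default_enrichment()
  enr["15N_RNA", ] <- c(0, 0, 2.0, 2.0, 0, 3.0)
  enr["13C_DNA", ] <- c(0, 0, 0.5, 0.5, 3.0, 0.2)
  truth <- build_scene(flat_scene_spec(shape = c(64L, 64L), lamina_width = 4,
                                       enrichment = enr))
  rna <- enrichment_image(truth$expected_counts, rds[["15N_RNA"]], 1)
  dna <- enrichment_image(truth$expected_counts, rds[["13C_DNA"]], 1)
  lp3 <- line_profile(list(RNA = rna, DNA = dna),
                      rbind(c(33, 2), c(33, 33)), width = 1)
  dna_peak <- which.max(lp3$samples$DNA)
  rna_rise <- min(which(lp3$samples$RNA >= 100))
  expect_lt(dna_peak, rna_rise)  # DNA rim precedes interior RNA, moving inward
})

test_that("unlabeled margin fraction follows the area formula with sign convention", {
  g <- function(n) { m <- matrix(FALSE, 20, 20); m[seq_len(n)] <- TRUE; m }
  d100 <- roi(g(100), "d"); r80 <- roi(g(80), "r")
  expect_equal(unlabeled_margin_fraction(d100, r80), 20)
  expect_equal(unlabeled_margin_fraction(d100, d100), 0)
  expect_warning(out <- unlabeled_margin_fraction(roi(g(80), "d"),
                                                  roi(g(100), "r")),
                 "negative")
  expect_equal(out, -25)
  # antisymmetry up to the denominator change; zero iff equal areas
  expect_equal(suppressWarnings(unlabeled_margin_fraction(r80, d100)) * 80,
               -unlabeled_margin_fraction(d100, r80) * 100)
})

test_that("threshold-traced laminar metric matches the rasterized geometry", {
  enr <- default_enrichment()
  enr["15N_RNA", ] <- c(0, 0, 2.0, 2.0, 0, 3.0)   # RNA-silent rim
  enr["13C_DNA", ] <- c(0, 0, 2.0, 2.0, 2.0, 2.0) # DNA uniform in nucleus
  spec <- scene_spec(image_shape = c(96L, 96L),
                     nucleus = list(center = c(48, 48), semi_axes = c(34, 27),
                                    angle = 0.4),
                     nucleoli = list(), lamina_width = 4,
                     chromatin = list(base = 1, n_foci = 0, amplitude = 0,
                                      radius = 2, correlation_length = 3,
                                      field_sd = 0),
                     enrichment = enr, count_budget = 500, seed = 1)
  truth <- build_scene(spec)
  cm <- truth$compartment_map
  a_nuc <- sum(cm >= truth$compartments[["nucleoplasm"]])
  a_inner <- sum(cm >= truth$compartments[["nucleoplasm"]] &
                 cm != truth$compartments[["lamina"]])
  geometric <- 100 * (a_nuc - a_inner) / a_nuc
  st <- sample_counts(truth, 11)
  dna <- labeled_area_roi(enrichment_image(st, rds[["13C_DNA"]], 20, smooth = 3),
                          30, "dna_trace")
  rna <- labeled_area_roi(enrichment_image(st, rds[["15N_RNA"]], 20, smooth = 3),
                          30, "rna_trace")
  expect_lt(abs(unlabeled_margin_fraction(dna, rna) - geometric), 2)
})

test_that("nucleolus detection: hit, centroid, size gate, and empty cases", {
  enr <- uniform_enrichment(0)
  enr["15N_RNA", ] <- c(0, 0.2, 1.0, 1.0, 1.0, 4.0)
  center <- c(30, 34)
  truth <- build_scene(flat_scene_spec(
    shape = c(64L, 64L), nucleoli = list(list(center = center, radius = 7.5)),
    enrichment = enr, count_budget = 800))
  st <- sample_counts(truth, 4)
  e <- enrichment_image(st, rds[["15N_RNA"]], 20, smooth = 3)
  nuc <- truth_roi(truth, "nucleus")
  hits <- nucleolus_detect(e, nuc, fold_threshold = 2)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$kind, "nucleolus")
  cen <- which(hits[[1]]$mask, arr.ind = TRUE)
  expect_lt(sqrt(sum((colMeans(cen) - center)^2)), 2)
  # masks strictly inside the nucleus
  expect_true(all(nuc$mask[hits[[1]]$mask]))
  # uniform nucleus -> empty list
  u <- build_scene(flat_scene_spec(enrichment = uniform_enrichment(1)))
  eu <- enrichment_image(u$expected_counts, rds[["15N_RNA"]], 1)
  expect_length(nucleolus_detect(eu, truth_roi(u, "nucleus"),
                                 pixel_size = 100), 0L)
  # bright speck of ~2 px below the 1 um diameter gate -> excluded
  sp <- truth$expected_counts
  sp[["12C15N"]][40, 40] <- sp[["12C14N"]][40, 40] * 0.037
  sp[["12C15N"]][40, 41] <- sp[["12C14N"]][40, 41] * 0.037
  es <- enrichment_image(sp, rds[["15N_RNA"]], 1)
  specks <- nucleolus_detect(es, nuc, fold_threshold = 2, pixel_size = 100)
  expect_false(any(vapply(specks, function(r) r$mask[40, 40], logical(1))))
})

test_that("fold enrichment: arithmetic, identity, and undefined reference", {
  vals <- matrix(100, 20, 20); vals[1:5, 1:5] <- 400
  e <- structure(list(values = vals, valid = matrix(TRUE, 20, 20),
                      ratio_def = rds[["15N_RNA"]], min_denominator = 1,
                      pixel_size = 100), class = "enrich_img")
  tgt <- roi({ m <- matrix(FALSE, 20, 20); m[1:5, 1:5] <- TRUE; m }, "t")
  ref <- roi({ m <- matrix(FALSE, 20, 20); m[6:20, ] <- TRUE; m }, "r")
  expect_equal(fold_enrichment(tgt, ref, e)$fold, 4)
  expect_equal(fold_enrichment(tgt, tgt, e)$fold, 1)
  zero <- structure(list(values = matrix(0, 20, 20),
                         valid = matrix(TRUE, 20, 20),
                         ratio_def = rds[["15N_RNA"]], min_denominator = 1,
                         pixel_size = 100), class = "enrich_img")
  expect_error(fold_enrichment(tgt, ref, zero), "not positive")
})
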