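# Shared fixtures, built in code.

rds <- tracer_definitions()

# A small flat scene: no texture, no foci, optional nucleoli.
flat_scene_spec <- function(shape = c(64L, 64L), semi_axes = c(24, 19),
                            nucleoli = list(), lamina_width = 2,
                            enrichment = default_enrichment(),
                            count_budget = 500, seed = 1L, angle = 0) {
  scene_spec(image_shape = shape, pixel_size = 100,
             nucleus = list(center = (shape + 1) / 2, semi_axes = semi_axes,
                            angle = angle),
             nucleoli = nucleoli, lamina_width = lamina_width,
             chromatin = list(base = 1, n_foci = 0, amplitude = 0, radius = 2,
                              correlation_length = 2, field_sd = 0),
             enrichment = enrichment, count_budget = count_budget,
             seed = seed)
}

# Enrichment matrix with every tracer at a single multiplier everywhere.
uniform_enrichment <- function(mult = 0) {
  m <- default_enrichment()
  m[] <- mult
  m
}

# Rasterized axis-aligned ellipse on an n x n grid.
ellipse_px <- function(n, center, semi) {
  r <- row(matrix(0, n, n)); c_ <- col(matrix(0, n, n))
  ((r - center[1]) / semi[1])^2 + ((c_ - center[2]) / semi[2])^2 <= 1
}

# Independent brute-force hotspot oracle: enumerate every k x k window fully
# inside the mask (and clear of the exclusion), score by ratio of summed
# counts, order by (-score, -den, row, col), then greedy-disjoint filter.
brute_force_hotspots <- function(num, den, mask, k, top_n, excl = NULL,
                                 disjoint = TRUE) {
  nr <- nrow(num); nc <- ncol(num)
  cand <- NULL
  for (r in 1:(nr - k + 1)) for (c_ in 1:(nc - k + 1)) {
    rr <- r:(r + k - 1); cc <- c_:(c_ + k - 1)
    if (!all(mask[rr, cc])) next
    if (!is.null(excl) && any(excl[rr, cc])) next
    sd_ <- sum(den[rr, cc])
    if (sd_ <= 0) next
    cand <- rbind(cand, c(r, c_, sum(num[rr, cc]) / sd_, sd_))
  }
  if (is.null(cand)) return(NULL)
  cand <- cand[order(-cand[, 3], -cand[, 4], cand[, 1], cand[, 2]), ,
               drop = FALSE]
  if (!disjoint) return(cand[seq_len(min(top_n, nrow(cand))), , drop = FALSE])
  occ <- matrix(FALSE, nr, nc); keep <- NULL
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c_ <- cand[i, 2]
    if (any(occ[r:(r + k - 1), c_:(c_ + k - 1)])) next
    occ[r:(r + k - 1), c_:(c_ + k - 1)] <- TRUE
    keep <- rbind(keep, cand[i, ])
    if (nrow(keep) == top_n) break
  }
  keep
}

# Independent closed-form OLS oracle (two-variable sum formulas).
ols_sums <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  b <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  a <- (sy - b * sx) / n
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}
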