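COMPARTMENTS <- c(background = 0L, cytoplasm = 1L, nucleoplasm = 2L,
                  chromatin_focus = 3L, lamina = 4L, nucleolus = 5L)
TRACERS <- c("15N_RNA", "13C_DNA", "2H_DNA", "81Br_DNA")

#' Synthetic scene specification
#'
#' Ground-truth geometry, labeling kinetics and count budget for the
#' simulator. A scene holds one cell: an elliptical nucleus with a laminar
#' rim of dense DNA, DNA-poor nucleoli with strongly elevated RNA label,
#' interior chromatin-density texture (a seeded correlated random field plus
#' hard dense foci), and surrounding cytoplasm. Each tracer is assigned a
#' per-compartment enrichment multiplier over natural background (0 = natural
#' abundance, 1.0 = 100 percent above background). Compartments partition
#' every pixel exactly once with priority nucleolus > lamina >
#' chromatin_focus > nucleoplasm > cytoplasm > background.
#'
#' Default conditions emulate a 120-min nucleoside pulse in a cultured
#' monocyte: nucleoli at 300 percent above background RNA label versus 100
#' percent in the nucleoplasm, a 3-px RNA-silent lamina with doubled DNA
#' label, and a denominator budget of 500 counts per pixel, which keeps the
#' nuclear-ROI relative standard error of enrichment below 2 percent.
#'
#' @param image_shape integer (rows, cols) in px.
#' @param pixel_size pixel edge in nm.
#' @param nucleus list: \code{center} (row, col), \code{semi_axes} (row, col
#'   semi-axis lengths in px), \code{angle} (radians).
#' @param nucleoli list of discs, each \code{list(center = c(row, col),
#'   radius = px >= 1)}; must lie wholly inside the nucleus.
#' @param lamina_width annular rim width in px inside the nuclear boundary.
#' @param cytoplasm_scale the cell boundary is the nucleus ellipse scaled by
#'   this factor; pixels between nucleus and cell are cytoplasm.
#' @param chromatin list: \code{base} level, \code{n_foci}, dense-focus
#'   \code{amplitude} and \code{radius} (px), \code{correlation_length} (px)
#'   and \code{field_sd} of the smooth density field. The density field is
#'   normalized to mean 1 over the nucleus and multiplies the DNA-tracer
#'   enrichment and the 31P structural channel; 32S is divided by it
#'   (phosphorus-rich, sulfur-poor chromatin).
#' @param enrichment numeric matrix, tracers x compartments (rownames from
#'   \code{"15N_RNA"}, \code{"13C_DNA"}, \code{"2H_DNA"}, \code{"81Br_DNA"};
#'   colnames the six compartments): multiplier over background, >= 0.
#' @param count_budget expected denominator-species counts per pixel inside
#'   the cell; scalar applied to all denominator species, or named vector.
#' @param structural_levels numeric matrix, compartments x c("31P", "32S"):
#'   expected counts per pixel.
#' @param br_unit expected 81Br counts per pixel per unit multiplier.
#' @param background_fraction denominator budget outside the cell, as a
#'   fraction of \code{count_budget}.
#' @param seed integer seed driving texture generation.
#' @return object of class \code{scene_spec}.
#' @export
scene_spec <- function(image_shape = c(128L, 128L), pixel_size = 100,
                       nucleus = list(center = c(64, 64),
                                      semi_axes = c(42, 34), angle = 0.3),
                       nucleoli = list(list(center = c(55, 55), radius = 7),
                                       list(center = c(75, 75), radius = 6)),
                       lamina_width = 3,
                       cytoplasm_scale = 1.45,
                       chromatin = list(base = 1, n_foci = 6, amplitude = 0.8,
                                        radius = 3, correlation_length = 4,
                                        field_sd = 0.25),
                       enrichment = default_enrichment(),
                       count_budget = 500,
                       structural_levels = default_structural_levels(),
                       br_unit = 50,
                       background_fraction = 0.1,
                       seed = 1L) {
  spec <- structure(list(image_shape = as.integer(image_shape),
                         pixel_size = pixel_size, nucleus = nucleus,
                         nucleoli = nucleoli, lamina_width = lamina_width,
                         cytoplasm_scale = cytoplasm_scale,
                         chromatin = chromatin, enrichment = enrichment,
                         count_budget = count_budget,
                         structural_levels = structural_levels,
                         br_unit = br_unit,
                         background_fraction = background_fraction,
                         seed = as.integer(seed)),
                    class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

#' Default per-compartment enrichment multipliers
#' @return tracers x compartments matrix of multipliers over background.
#' @export
default_enrichment <- function() {
  m <- rbind(
    `15N_RNA`  = c(background = 0, cytoplasm = 0.3, nucleoplasm = 1.0,
                   chromatin_focus = 0.6, lamina = 0.1, nucleolus = 3.0),
    `13C_DNA`  = c(0, 0, 1.0, 2.0, 2.0, 0.15),
    `2H_DNA`   = c(0, 0, 1.0, 2.0, 2.0, 0.15),
    `81Br_DNA` = c(0, 0, 1.0, 2.0, 2.0, 0.15))
  colnames(m) <- names(COMPARTMENTS)
  m
}

#' Default structural 31P/32S levels (expected counts per pixel)
#' @return compartments x species matrix.
#' @export
default_structural_levels <- function() {
  m <- cbind(`31P` = c(background = 0.5, cytoplasm = 30, nucleoplasm = 80,
                       chromatin_focus = 100, lamina = 110, nucleolus = 40),
             `32S` = c(0.5, 100, 60, 40, 40, 70))
  m
}

validate_scene_spec <- function(spec) {
  s <- spec
  if (length(s$image_shape) != 2L || any(s$image_shape < 1L))
    stop("image_shape must be two positive integers", call. = FALSE)
  if (any(s$enrichment < 0))
    stop("enrichment multipliers must be >= 0", call. = FALSE)
  if (!all(TRACERS %in% rownames(s$enrichment)))
    stop("enrichment matrix must cover all four tracers", call. = FALSE)
  if (!all(names(COMPARTMENTS) %in% colnames(s$enrichment)))
    stop("enrichment matrix must cover all six compartments", call. = FALSE)
  if (any(unlist(s$count_budget) < 0) || s$background_fraction < 0)
    stop("count budgets must be >= 0", call. = FALSE)
  if (s$lamina_width < 0) stop("lamina_width must be >= 0", call. = FALSE)
  if (s$lamina_width >= min(s$nucleus$semi_axes))
    stop("geometry error: lamina width leaves no nuclear interior",
         call. = FALSE)
  nuc <- ellipse_mask(s$image_shape, s$nucleus$center, s$nucleus$semi_axes,
                      s$nucleus$angle)
  for (nl in s$nucleoli) {
    if (nl$radius < 1) stop("nucleolus radius must be >= 1 px", call. = FALSE)
    dm <- disc_mask(s$image_shape, nl$center, nl$radius)
    if (any(dm & !nuc))
      stop("geometry error: nucleolus extends outside the nucleus ellipse",
           call. = FALSE)
  }
  invisible(spec)
}

# Rasterized ellipse membership mask (row/col plane, rotated by angle).
ellipse_mask <- function(shape, center, semi_axes, angle = 0) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c_ <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  dr <- r - center[1L]; dc <- c_ - center[2L]
  u <- cos(angle) * dr + sin(angle) * dc
  v <- -sin(angle) * dr + cos(angle) * dc
  (u / semi_axes[1L])^2 + (v / semi_axes[2L])^2 <= 1
}

disc_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c_ <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  (r - center[1L])^2 + (c_ - center[2L])^2 <= radius^2
}

# Seeded smooth correlated field, standardized over a mask.
smooth_field <- function(shape, correlation_length, seed, mask = NULL) {
  set.seed(seed)
  w <- matrix(stats::rnorm(prod(shape)), shape[1L], shape[2L])
  if (correlation_length > 0) {
    img <- EBImage::gblur(EBImage::Image(t(w)), sigma = correlation_length)
    w <- t(EBImage::imageData(img))
  }
  sel <- if (is.null(mask)) rep(TRUE, length(w)) else mask
  mu <- mean(w[sel]); sg <- stats::sd(w[sel])
  if (!is.finite(sg) || sg == 0) sg <- 1
  (w - mu) / sg
}

#' Build the ground truth for a scene
#'
#' Deterministic given the spec (the only randomness is the seeded chromatin
#' texture). Produces the per-pixel compartment map, the chromatin density
#' field, the expected (Poisson-mean) count grid for every species and the
#' expected percent-above-background enrichment grid for each ratio tracer.
#' By construction, running the ratio engine on the expected counts recovers
#' the expected enrichment exactly: for tracer multiplier m the expected
#' numerator/denominator ratio is R0 * (1 + m).
#'
#' @param spec a [scene_spec()].
#' @param tracer_defs ratio definitions supplying species names and R0,
#'   from [tracer_definitions()].
#' @return object of class \code{scene_truth}: list with
#'   \code{compartment_map} (integer matrix, legend in
#'   \code{compartments}), \code{density}, \code{expected_counts} (named list
#'   of matrices), \code{expected_enrichment} (named list, percent above
#'   background per ratio tracer plus \code{81Br_DNA}), \code{pixel_size},
#'   \code{spec}.
#' @export
build_scene <- function(spec, tracer_defs = tracer_definitions()) {
  validate_scene_spec(spec)
  shape <- spec$image_shape
  nuc <- ellipse_mask(shape, spec$nucleus$center, spec$nucleus$semi_axes,
                      spec$nucleus$angle)
  cell <- ellipse_mask(shape, spec$nucleus$center,
                       spec$nucleus$semi_axes * spec$cytoplasm_scale,
                       spec$nucleus$angle)
  inner <- ellipse_mask(shape, spec$nucleus$center,
                        pmax(spec$nucleus$semi_axes - spec$lamina_width, 0.5),
                        spec$nucleus$angle)
  lam <- nuc & !inner

  # chromatin dense foci: seeded disc placement inside the inner nucleus
  set.seed(spec$seed + 1L)
  foci <- matrix(FALSE, shape[1L], shape[2L])
  ch <- spec$chromatin
  if (ch$n_foci > 0) {
    cand <- which(inner, arr.ind = TRUE)
    idx <- cand[sample(nrow(cand), min(ch$n_foci, nrow(cand))), , drop = FALSE]
    for (i in seq_len(nrow(idx)))
      foci <- foci | (disc_mask(shape, idx[i, ], ch$radius) & inner)
  }

  comp <- matrix(COMPARTMENTS[["background"]], shape[1L], shape[2L])
  comp[cell] <- COMPARTMENTS[["cytoplasm"]]
  comp[nuc] <- COMPARTMENTS[["nucleoplasm"]]
  comp[foci] <- COMPARTMENTS[["chromatin_focus"]]
  comp[lam] <- COMPARTMENTS[["lamina"]]
  for (nl in spec$nucleoli)
    comp[disc_mask(shape, nl$center, nl$radius)] <- COMPARTMENTS[["nucleolus"]]

  # chromatin density: base + focus amplitude + smooth correlated field,
  # clipped positive and normalized to mean 1 over the nucleus
  d <- matrix(1, shape[1L], shape[2L])
  f <- smooth_field(shape, ch$correlation_length, spec$seed, mask = nuc)
  draw <- ch$base + ch$amplitude * foci + ch$field_sd * f
  draw <- pmax(draw, 0.05)
  d[nuc] <- draw[nuc] / mean(draw[nuc])

  comp_name <- names(COMPARTMENTS)[match(comp, COMPARTMENTS)]
  budget_of <- function(sp) {
    b <- spec$count_budget
    if (length(b) == 1L && is.null(names(b))) return(unname(b))
    if (!sp %in% names(b))
      stop(sprintf("no count budget for denominator species %s", sp),
           call. = FALSE)
    unname(b[[sp]])
  }

  expected <- list(); enr <- list()
  cellish <- cell | nuc
  for (tr in c("15N_RNA", "13C_DNA", "2H_DNA")) {
    rd <- tracer_defs[[tr]]
    mult <- matrix(spec$enrichment[tr, comp_name], shape[1L], shape[2L])
    if (tr != "15N_RNA") mult <- mult * d  # DNA label follows chromatin density
    den <- matrix(budget_of(rd$denominator), shape[1L], shape[2L])
    den[!cellish] <- den[!cellish] * spec$background_fraction
    num <- den * rd$R0 * (1 + mult)
    if (is.null(expected[[rd$denominator]])) expected[[rd$denominator]] <- den
    expected[[rd$numerator]] <- num
    enr[[tr]] <- 100 * mult
  }
  br_mult <- matrix(spec$enrichment["81Br_DNA", comp_name],
                    shape[1L], shape[2L]) * d
  expected[["81Br"]] <- 0.5 + spec$br_unit * br_mult
  enr[["81Br_DNA"]] <- 100 * br_mult

  sl <- spec$structural_levels
  expected[["31P"]] <- matrix(sl[comp_name, "31P"], shape[1L], shape[2L]) * d
  expected[["32S"]] <- matrix(sl[comp_name, "32S"], shape[1L], shape[2L]) / d

  structure(list(compartment_map = comp, compartments = COMPARTMENTS,
                 density = d, expected_counts = expected,
                 expected_enrichment = enr, pixel_size = spec$pixel_size,
                 spec = spec),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  d <- dim(x$compartment_map)
  cat(sprintf("scene_truth: %d x %d px, %d species, compartments:\n",
              d[1L], d[2L], length(x$expected_counts)))
  print(table(names(x$compartments)[match(x$compartment_map,
                                          x$compartments)]))
  invisible(x)
}

#' Sample an ion-count stack from a scene's ground truth
#'
#' Each pixel-species count is drawn independently from a Poisson law with
#' the expected-count mean; an identical seed yields a bit-identical stack.
#'
#' @param truth a [build_scene()] result.
#' @param seed integer seed for the Poisson draw.
#' @return a [mass_stack()] carrying species names and pixel size.
#' @export
sample_counts <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"))
  set.seed(seed)
  chans <- lapply(truth$expected_counts, function(mu) {
    if (any(mu < 0)) stop("expected counts must be >= 0", call. = FALSE)
    matrix(stats::rpois(length(mu), as.vector(mu)), nrow(mu), ncol(mu))
  })
  mass_stack(chans, pixel_size = truth$pixel_size,
             metadata = list(simulated = TRUE, seed = seed))
}

#' Ground-truth ROI for a compartment
#'
#' @param truth a [build_scene()] result.
#' @param compartment compartment name.
#' @return an [roi()] for that compartment, or for the whole nucleus when
#'   \code{compartment = "nucleus"} (nucleoplasm + lamina + foci + nucleoli).
#' @export
truth_roi <- function(truth, compartment) {
  cm <- truth$compartment_map
  if (compartment == "nucleus") {
    m <- cm >= COMPARTMENTS[["nucleoplasm"]]
    kind <- "nucleus"
  } else {
    m <- cm == COMPARTMENTS[[compartment]]
    kind <- switch(compartment, nucleolus = "nucleolus",
                   lamina = "lamina_margin", cytoplasm = "cytoplasm", "custom")
  }
  roi(m, label = compartment, kind = kind, provenance = "ground truth")
}

#' Per-compartment summary of a scene's ground truth
#'
#' Pure aggregation: one row per compartment present, with pixel and
#' micrometre-squared areas and each tracer's mean expected enrichment.
#'
#' @param truth a [build_scene()] result.
#' @return data.frame.
#' @export
scene_truth_summary <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  cm <- truth$compartment_map
  px_um2 <- (truth$pixel_size / 1000)^2
  present <- names(truth$compartments)[truth$compartments %in% unique(as.vector(cm))]
  rows <- lapply(present, function(cp) {
    sel <- cm == truth$compartments[[cp]]
    out <- data.frame(compartment = cp, area_px = sum(sel),
                      area_um2 = sum(sel) * px_um2, stringsAsFactors = FALSE)
    for (tr in names(truth$expected_enrichment))
      out[[paste0("enrichment_", tr)]] <- mean(truth$expected_enrichment[[tr]][sel])
    out
  })
  do.call(rbind, rows)
}

#' Synthetic scene with a prescribed DNA-RNA pixel slope
#'
#' Builds a nucleus whose DNA enrichment field is a smooth seeded texture
#' scaled to \code{dna_range}, with RNA enrichment set to
#' \code{intercept + slope * DNA} pixel-wise — the ground truth for
#' regression-recovery experiments. Outside the nucleus both tracers sit at
#' natural abundance.
#'
#' @param image_shape (rows, cols) px.
#' @param slope,intercept the prescribed linear relation (percent RNA
#'   enrichment per percent DNA enrichment; percent).
#' @param dna_range range (percent above background) spanned by the DNA
#'   enrichment field inside the nucleus.
#' @param count_budget denominator counts per pixel for both ratio pairs.
#' @param correlation_length texture smoothness (px).
#' @param pixel_size nm per px.
#' @param seed texture seed.
#' @param tracer_defs ratio definitions for the two tracers.
#' @return a \code{scene_truth} (compartments: nucleoplasm inside, background
#'   outside) usable with [sample_counts()].
#' @export
regression_scene <- function(image_shape = c(48L, 48L), slope = 0,
                             intercept = 100, dna_range = c(50, 150),
                             count_budget = 2000, correlation_length = 3,
                             pixel_size = 100, seed = 1L,
                             tracer_defs = tracer_definitions()) {
  shape <- as.integer(image_shape)
  ctr <- (shape + 1) / 2
  nuc <- ellipse_mask(shape, ctr, shape / 2 - 2, 0)
  f <- smooth_field(shape, correlation_length, seed, mask = nuc)
  fr <- range(f[nuc])
  dna <- matrix(0, shape[1L], shape[2L])
  dna[nuc] <- dna_range[1L] + (f[nuc] - fr[1L]) / diff(fr) * diff(dna_range)
  rna <- matrix(0, shape[1L], shape[2L])
  rna[nuc] <- intercept + slope * dna[nuc]
  if (any(rna < 0))
    stop("intercept/slope produce negative RNA enrichment; adjust intercept",
         call. = FALSE)
  comp <- matrix(COMPARTMENTS[["background"]], shape[1L], shape[2L])
  comp[nuc] <- COMPARTMENTS[["nucleoplasm"]]
  rd_n <- tracer_defs[["15N_RNA"]]; rd_c <- tracer_defs[["13C_DNA"]]
  den <- matrix(count_budget, shape[1L], shape[2L])
  expected <- list()
  expected[[rd_n$denominator]] <- den
  expected[[rd_n$numerator]] <- den * rd_n$R0 * (1 + rna / 100)
  expected[[rd_c$denominator]] <- den
  expected[[rd_c$numerator]] <- den * rd_c$R0 * (1 + dna / 100)
  structure(list(compartment_map = comp, compartments = COMPARTMENTS,
                 density = matrix(1, shape[1L], shape[2L]),
                 expected_counts = expected,
                 expected_enrichment = list(`15N_RNA` = rna, `13C_DNA` = dna),
                 pixel_size = pixel_size,
                 spec = list(slope = slope, intercept = intercept,
                             dna_range = dna_range,
                             count_budget = count_budget, seed = seed)),
            class = "scene_truth")
}
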