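ROI_KINDS <- c("nucleus", "cytoplasm", "nucleolus", "lamina_margin",
               "hotspot", "custom")

#' Region of interest
#'
#' A labeled pixel set on the stack grid: a boolean mask plus a kind from the
#' closed set nucleus / cytoplasm / nucleolus / lamina_margin / hotspot /
#' custom, and a provenance string recording how it was derived.
#'
#' @param mask logical matrix, same shape as the stack; must select at least
#'   one pixel.
#' @param label name of the ROI.
#' @param kind one of \code{"nucleus"}, \code{"cytoplasm"}, \code{"nucleolus"},
#'   \code{"lamina_margin"}, \code{"hotspot"}, \code{"custom"}.
#' @param provenance how the ROI was derived (channel + rule, or manual spec).
#' @return object of class \code{roi}.
#' @export
roi <- function(mask, label = "roi", kind = "custom", provenance = "manual") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (sum(mask) == 0L)
    stop("ROI mask is empty", call. = FALSE)
  kind <- match.arg(kind, ROI_KINDS)
  structure(list(mask = mask, label = label, kind = kind,
                 provenance = provenance),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi '%s' (%s): %d px, %s\n", x$label, x$kind, sum(x$mask),
              x$provenance))
  invisible(x)
}

#' ROI area
#'
#' @param x an [roi()].
#' @param pixel_size pixel edge in nm; if given, the area is also returned in
#'   square micrometres.
#' @return named numeric: \code{area_px} and (if pixel_size given)
#'   \code{area_um2}.
#' @export
roi_area <- function(x, pixel_size = NULL) {
  a <- c(area_px = sum(x$mask))
  if (!is.null(pixel_size))
    a <- c(a, area_um2 = sum(x$mask) * (pixel_size / 1000)^2)
  a
}

#' Segment the nucleus (or whole cell) from a structural channel
#'
#' Thresholds a structural ion channel with an automatically chosen
#' (Otsu-style bimodal) cutoff after light Gaussian smoothing, fills holes and
#' keeps the largest connected component. The threshold is data-relative, so
#' segmentation is invariant to multiplying the channel by a positive
#' constant. Strategies: \code{P_threshold} segments the phosphorus-rich
#' nucleus from 31P; \code{S_contour} and \code{CN_contour} segment the whole
#' cell body from 32S or 12C14N (the cytoplasm ROI is then cell minus
#' nucleus).
#'
#' @param stack a [mass_stack()].
#' @param strategy \code{"P_threshold"}, \code{"S_contour"} or
#'   \code{"CN_contour"}.
#' @param min_area smallest acceptable component (px); if no component
#'   reaches it, a segmentation failure error is signalled.
#' @param sigma Gaussian smoothing sigma in px applied before thresholding.
#' @return an [roi()] of kind nucleus (P_threshold) or custom (cell body).
#' @export
segment_nucleus <- function(stack, strategy = c("P_threshold", "S_contour",
                                                "CN_contour"),
                            min_area = 50L, sigma = 1) {
  strategy <- match.arg(strategy)
  species <- switch(strategy, P_threshold = "31P", S_contour = "32S",
                    CN_contour = "12C14N")
  comps <- segment_components(stack, species, min_area, sigma)
  if (length(comps) == 0L)
    stop(sprintf("segmentation failure: no connected component >= %d px in %s",
                 min_area, species), call. = FALSE)
  areas <- vapply(comps, sum, numeric(1L))
  kind <- if (strategy == "P_threshold") "nucleus" else "custom"
  roi(comps[[which.max(areas)]], label = strategy, kind = kind,
      provenance = sprintf("%s otsu threshold, largest component", species))
}

#' Segment all nuclei in the frame
#'
#' Multi-instance variant of [segment_nucleus()]: returns every connected
#' component at least \code{min_area} px, as disjoint ROIs ordered by
#' decreasing area.
#'
#' @inheritParams segment_nucleus
#' @return list of [roi()] objects (possibly empty).
#' @export
segment_nuclei <- function(stack, strategy = c("P_threshold", "S_contour",
                                               "CN_contour"),
                           min_area = 50L, sigma = 1) {
  strategy <- match.arg(strategy)
  species <- switch(strategy, P_threshold = "31P", S_contour = "32S",
                    CN_contour = "12C14N")
  comps <- segment_components(stack, species, min_area, sigma)
  comps <- comps[order(-vapply(comps, sum, numeric(1L)))]
  kind <- if (strategy == "P_threshold") "nucleus" else "custom"
  lapply(seq_along(comps), function(i)
    roi(comps[[i]], label = sprintf("%s_%d", strategy, i), kind = kind,
        provenance = sprintf("%s otsu threshold, component %d", species, i)))
}

# Shared segmentation core: smooth, Otsu, fill holes, label components.
segment_components <- function(stack, species, min_area, sigma) {
  ch <- stack_channel(stack, species)
  if (max(ch) <= 0)
    stop(sprintf("segmentation failure: channel %s is blank", species),
         call. = FALSE)
  img <- EBImage::Image(t(ch / max(ch)))  # EBImage is x,y ordered
  if (sigma > 0) img <- EBImage::gblur(img, sigma = sigma)
  img <- (img - min(img)) / max(1e-12, diff(range(img)))
  thr <- EBImage::otsu(img, range = c(0, 1))
  bin <- EBImage::fillHull(img > thr)
  lab <- EBImage::bwlabel(bin)
  labm <- t(EBImage::imageData(lab))
  ids <- setdiff(unique(as.vector(labm)), 0)
  comps <- lapply(ids, function(i) labm == i)
  comps[vapply(comps, sum, numeric(1L)) >= min_area]
}

#' Derive the cytoplasm ROI as cell body minus nucleus
#'
#' @param cell,nucleus [roi()] objects on the same grid.
#' @return an [roi()] of kind cytoplasm.
#' @export
cytoplasm_roi <- function(cell, nucleus) {
  m <- cell$mask & !nucleus$mask
  roi(m, label = "cytoplasm", kind = "cytoplasm",
      provenance = sprintf("%s minus %s", cell$label, nucleus$label))
}

#' Threshold-traced labeled-area ROI
#'
#' Reproducible stand-in for manually tracing the visibly labeled area on an
#' enrichment image: pixels at or above a fixed percent-above-background
#' threshold, holes filled, largest connected component kept. Pair a
#' DNA-guided and an RNA-guided trace to compute the laminar unlabeled-area
#' metric with [unlabeled_margin_fraction()].
#'
#' @param enr an [enrichment_image()] (typically computed with
#'   \code{smooth = 3} so single-pixel shot noise does not fragment the trace).
#' @param threshold percent above background counted as labeled (default 30).
#' @param label,kind passed to [roi()].
#' @return an [roi()].
#' @export
labeled_area_roi <- function(enr, threshold = 30, label = "labeled",
                             kind = "custom") {
  stopifnot(inherits(enr, "enrich_img"))
  bin <- enr$valid & !is.na(enr$values) & enr$values >= threshold
  if (sum(bin) == 0L)
    stop(sprintf("no pixels at or above %g%% enrichment", threshold),
         call. = FALSE)
  # 3x3 opening removes isolated shot-noise speckles before tracing
  img <- EBImage::opening(EBImage::Image(t(bin)),
                          EBImage::makeBrush(3L, "box"))
  img <- EBImage::fillHull(img)
  lab <- t(EBImage::imageData(EBImage::bwlabel(img)))
  ids <- setdiff(unique(as.vector(lab)), 0)
  areas <- vapply(ids, function(i) sum(lab == i), numeric(1L))
  roi(lab == ids[which.max(areas)], label = label, kind = kind,
      provenance = sprintf("%s >= %g%% threshold trace", enr$ratio_def$label,
                           threshold))
}

#' Unlabeled margin fraction
#'
#' The laminar silencing metric: the percent of the DNA-traced nuclear area
#' not covered by the RNA-traced area,
#' 100 * (area(DNA) - area(RNA)) / area(DNA). Negative values (RNA-guided
#' area exceeding DNA-guided) are reported with a warning, never clamped.
#'
#' @param dna_roi,rna_roi [roi()] objects on the same grid.
#' @return percent unlabeled (scalar).
#' @export
unlabeled_margin_fraction <- function(dna_roi, rna_roi) {
  a_dna <- sum(dna_roi$mask); a_rna <- sum(rna_roi$mask)
  if (a_dna == 0L) stop("DNA ROI is empty", call. = FALSE)
  if (!all(dim(dna_roi$mask) == dim(rna_roi$mask)))
    stop("ROIs are on different grids", call. = FALSE)
  out <- 100 * (a_dna - a_rna) / a_dna
  if (out < 0)
    warning("RNA-guided area exceeds DNA-guided area; fraction is negative",
            call. = FALSE)
  out
}

#' Detect putative nucleoli
#'
#' Connected components inside the nucleus whose mean RNA enrichment reaches
#' \code{fold_threshold} times the nuclear mean and whose equivalent diameter
#' lies in the given range (default 1-3 micrometres, the size of nucleoli).
#' The returned masks are disjoint and strictly inside the nucleus; the union
#' is the usual nucleolar exclusion mask for non-nucleolar pixel analyses.
#'
#' @param rna_enr an [enrichment_image()] of the RNA tracer.
#' @param nucleus nucleus [roi()].
#' @param fold_threshold multiple of the nuclear mean enrichment a component
#'   must reach (default 2).
#' @param min_diameter_um,max_diameter_um equivalent-diameter gate in
#'   micrometres.
#' @param pixel_size nm per px; defaults to the enrichment image's.
#' @return list of [roi()] objects of kind nucleolus (possibly empty).
#' @export
nucleolus_detect <- function(rna_enr, nucleus, fold_threshold = 2,
                             min_diameter_um = 1, max_diameter_um = 3,
                             pixel_size = rna_enr$pixel_size) {
  stopifnot(inherits(rna_enr, "enrich_img"), inherits(nucleus, "roi"))
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size (nm) required to apply the diameter gate", call. = FALSE)
  sel <- nucleus$mask & rna_enr$valid
  nuc_mean <- mean(rna_enr$values[sel])
  if (!is.finite(nuc_mean) || nuc_mean <= 0) return(list())
  cand <- sel & !is.na(rna_enr$values) & rna_enr$values >= fold_threshold * nuc_mean
  if (sum(cand) == 0L) return(list())
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(cand)))))
  ids <- setdiff(unique(as.vector(lab)), 0)
  px_um <- pixel_size / 1000
  out <- list()
  for (i in ids) {
    m <- lab == i
    diam_um <- 2 * sqrt(sum(m) / pi) * px_um
    mean_enr <- mean(rna_enr$values[m & rna_enr$valid])
    if (diam_um >= min_diameter_um && diam_um <= max_diameter_um &&
        is.finite(mean_enr) && mean_enr >= fold_threshold * nuc_mean)
      out[[length(out) + 1L]] <- roi(m, label = sprintf("nucleolus_%d",
                                                        length(out) + 1L),
                                     kind = "nucleolus",
                                     provenance = sprintf(
                                       ">= %gx nuclear mean, diameter %.2f um",
                                       fold_threshold, diam_um))
  }
  out
}

#' Fold enrichment of a target ROI over a reference ROI
#'
#' Mean valid-pixel enrichment of the target divided by that of the reference
#' (typically the whole nucleus). Reported only when the reference mean is
#' positive. The standard error is propagated from the pixel-level standard
#' errors of the two means (delta method).
#'
#' @param target,reference [roi()] objects.
#' @param enr an [enrichment_image()].
#' @return list: \code{fold}, \code{se}, \code{target_mean},
#'   \code{reference_mean}, \code{n_target}, \code{n_reference}.
#' @export
fold_enrichment <- function(target, reference, enr) {
  stopifnot(inherits(enr, "enrich_img"))
  tv <- enr$values[target$mask & enr$valid]
  rv <- enr$values[reference$mask & enr$valid]
  if (length(rv) == 0L || mean(rv) <= 0)
    stop("reference mean enrichment is not positive; fold undefined",
         call. = FALSE)
  mt <- mean(tv); mr <- mean(rv)
  fold <- mt / mr
  se_t <- stats::sd(tv) / sqrt(length(tv))
  se_r <- stats::sd(rv) / sqrt(length(rv))
  se <- abs(fold) * sqrt((se_t / mt)^2 + (se_r / mr)^2)
  list(fold = fold, se = se, target_mean = mt, reference_mean = mr,
       n_target = length(tv), n_reference = length(rv))
}

#' Line profile across an image
#'
#' Samples values along a polyline at 1 px steps with nearest-pixel lookup,
#' averaging over a perpendicular width. Invalid pixels of enrichment images
#' never contribute to the means.
#'
#' @param images named list of [enrichment_image()] objects and/or plain
#'   matrices (raw channels).
#' @param polyline n x 2 matrix of (row, col) vertices, 1-based; must lie
#'   inside the image together with its perpendicular width band.
#' @param width perpendicular averaging width in px (>= 1).
#' @return object of class \code{line_profile}: list with \code{position}
#'   (px along the path), \code{position_nm} when pixel size is known,
#'   \code{samples} (named list of numeric vectors, one per image).
#' @export
line_profile <- function(images, polyline, width = 1L) {
  stopifnot(is.matrix(polyline), ncol(polyline) == 2L, nrow(polyline) >= 2L,
            width >= 1L)
  if (is.null(names(images))) names(images) <- paste0("ch", seq_along(images))
  grids <- lapply(images, function(im)
    if (inherits(im, "enrich_img")) im$values else im)
  d <- dim(grids[[1L]])
  px_nm <- NA_real_
  for (im in images)
    if (inherits(im, "enrich_img") && is.finite(im$pixel_size))
      px_nm <- im$pixel_size
  # sample points at 1 px spacing along segments
  pts <- NULL; perp <- NULL
  for (s in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[s, ]; b <- polyline[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    tseq <- seq(0, len, by = 1)
    u <- (b - a) / len
    seg <- cbind(a[1L] + tseq * u[1L], a[2L] + tseq * u[2L])
    if (s > 1L) { seg <- seg[-1L, , drop = FALSE] }
    pts <- rbind(pts, seg)
    perp <- rbind(perp, matrix(c(-u[2L], u[1L]), nrow(seg), 2L, byrow = TRUE))
  }
  offs <- seq_len(width) - (width + 1) / 2
  samples <- lapply(grids, function(g) numeric(nrow(pts)))
  for (p in seq_len(nrow(pts))) {
    rr <- round(pts[p, 1L] + offs * perp[p, 1L])
    cc <- round(pts[p, 2L] + offs * perp[p, 2L])
    if (any(rr < 1L | rr > d[1L] | cc < 1L | cc > d[2L]))
      stop("polyline (with its width band) exits the image", call. = FALSE)
    for (k in seq_along(grids)) {
      v <- grids[[k]][cbind(rr, cc)]
      samples[[k]][p] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  pos <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  structure(list(position = pos,
                 position_nm = if (is.finite(px_nm)) pos * px_nm else NULL,
                 samples = samples, width = width),
            class = "line_profile")
}

#' Per-ROI statistics table
#'
#' One row per ROI with area and, for each tracer, the pooled ratio,
#' enrichment and Poisson SE — the export from which standard inferential
#' routines (ANOVA, t tests) are run downstream.
#'
#' @param stack a [mass_stack()].
#' @param rois list of [roi()] objects.
#' @param rds list of [ratio_definition()] objects.
#' @return data.frame, one row per ROI x tracer.
#' @export
roi_stats_table <- function(stack, rois, rds = tracer_definitions()) {
  rows <- list()
  for (r in rois) for (rd in rds) {
    if (!all(c(rd$numerator, rd$denominator) %in% names(stack$channels))) next
    p <- pooled_roi_ratio(stack, r, rd)
    rows[[length(rows) + 1L]] <- data.frame(
      label = r$label, kind = r$kind, area_px = sum(r$mask),
      area_um2 = sum(r$mask) * (stack$pixel_size / 1000)^2,
      tracer = rd$label, ratio = p$ratio, ratio_x1e4 = ratio_to_scaled(p$ratio),
      enrichment_pct = p$enrichment, enrichment_se = p$enrichment_se,
      mean_pixel_enrichment = p$mean_pixel_enrichment,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
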