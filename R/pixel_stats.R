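#' Pixel-wise linear regression between two images
#'
#' Ordinary least squares of y on x over jointly valid pixels in a mask —
#' the per-cell DNA-vs-RNA (or proxy-density-vs-RNA) pixel correlation.
#' Pixels are treated as independent observations, as in conventional
#' single-cell MIMS analyses; no spatial autocorrelation correction is
#' applied (see the methods vignette).
#'
#' @param x regressor: [enrichment_image()], or a plain numeric matrix
#'   (e.g. a P/S proxy grid or raw 81Br counts; slopes are then per proxy
#'   unit).
#' @param y response [enrichment_image()] or numeric matrix.
#' @param mask [roi()] or logical matrix restricting the pixels.
#' @param cell_id provenance tag carried into the result.
#' @return object of class \code{pixel_fit}: slope, intercept, r_squared,
#'   p_value (two-sided, slope = 0), n, cell_id, and the underlying
#'   \code{lm} fit.
#' @export
pixel_regression <- function(x, y, mask = NULL, cell_id = NA_character_) {
  gx <- if (inherits(x, "enrich_img")) x$values else x
  gy <- if (inherits(y, "enrich_img")) y$values else y
  stopifnot(all(dim(gx) == dim(gy)))
  sel <- !is.na(gx) & !is.na(gy)
  if (inherits(x, "enrich_img")) sel <- sel & x$valid
  if (inherits(y, "enrich_img")) sel <- sel & y$valid
  if (!is.null(mask)) {
    m <- if (inherits(mask, "roi")) mask$mask else mask
    sel <- sel & m
  }
  n <- sum(sel)
  if (n < 3L)
    stop("fewer than 3 jointly valid pixels; regression undefined",
         call. = FALSE)
  xv <- gx[sel]; yv <- gy[sel]
  if (stats::sd(xv) == 0)
    stop("degenerate design: regressor is constant over the masked pixels",
         call. = FALSE)
  if (stats::sd(yv) == 0)  # flat response: slope exactly 0, nothing explained
    return(structure(list(slope = 0, intercept = yv[1L], r_squared = 0,
                          p_value = 1, slope_ci = c(0, 0), n = n,
                          cell_id = cell_id, fit = NULL),
                     class = "pixel_fit"))
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2L, 4L],
                 slope_ci = unname(stats::confint(fit)[2L, ]),
                 n = n, cell_id = cell_id, fit = fit),
            class = "pixel_fit")
}

#' @export
print.pixel_fit <- function(x, ...) {
  cat(sprintf("pixel_fit%s: slope = %.3g [%.3g, %.3g], R2 = %.3g, p = %.3g, n = %d\n",
              if (is.na(x$cell_id)) "" else paste0(" (", x$cell_id, ")"),
              x$slope, x$slope_ci[1L], x$slope_ci[2L], x$r_squared,
              x$p_value, x$n))
  invisible(x)
}

#' Robust and classical dispersion of a pixel population
#'
#' The median absolute deviation is the raw median(|v - median(v)|), without
#' the 1.4826 normal-consistency constant: it is used comparatively between
#' pixel distributions, where the constant cancels. The coefficient of
#' variation uses the sample (n - 1) standard deviation and is defined only
#' for a positive mean.
#'
#' @param values numeric vector of per-pixel enrichments (NA dropped).
#' @return object of class \code{dispersion_stats}: median, mad (raw), mean,
#'   sd, cov, n.
#' @export
dispersion <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 1L) stop("no values", call. = FALSE)
  med <- stats::median(v)
  madr <- stats::median(abs(v - med))
  mu <- mean(v)
  s <- if (length(v) > 1L) stats::sd(v) else NA_real_
  cv <- if (is.na(s)) NA_real_ else if (mu > 0) s / mu else {
    warning("cov undefined: mean is not positive", call. = FALSE)
    NA_real_
  }
  structure(list(median = med, mad = madr, mean = mu, sd = s, cov = cv,
                 n = length(v), mad_consistency_constant = "none (raw MAD)"),
            class = "dispersion_stats")
}

#' @export
print.dispersion_stats <- function(x, ...) {
  cat(sprintf("dispersion (n = %d): median %.4g, MAD %.4g (raw), mean %.4g, sd %.4g, COV %.4g\n",
              x$n, x$median, x$mad, x$mean, x$sd, x$cov))
  invisible(x)
}

#' Top-percentile density subset and companion-tracer summary
#'
#' Selects the masked pixels whose density reaches the nearest-rank cutoff
#' for the top \code{pct} percent (ties at the cutoff are all included, so
#' the subset may exceed pct * n / 100 pixels) and summarises the companion
#' tracer within the subset: pooled ratio and mean-of-pixel enrichment, plus
#' the natural-background reference value on the x 10^4 scale (37 for
#' 15N/14N) for the reference line.
#'
#' @param density [enrichment_image()] or numeric matrix (e.g. raw 81Br
#'   counts or a P/S grid) defining DNA density.
#' @param mask [roi()] or logical matrix.
#' @param pct top percentage (0 < pct < 100), default 5.
#' @param stack,companion_rd when given, the companion tracer's pooled
#'   enrichment within the subset is computed from the stack with this
#'   [ratio_definition()].
#' @return list: \code{roi} (the subset), \code{cutoff}, \code{n_subset},
#'   \code{n_mask}, and when the companion is requested: \code{companion}
#'   (the [pooled_roi_ratio()] list), \code{background_scaled} (R0 x 1e4).
#' @export
top_percentile_subset <- function(density, mask, pct = 5,
                                  stack = NULL, companion_rd = NULL) {
  if (pct <= 0 || pct >= 100) stop("pct must be in (0, 100)", call. = FALSE)
  g <- if (inherits(density, "enrich_img")) density$values else density
  m <- if (inherits(mask, "roi")) mask$mask else mask
  sel <- m & !is.na(g)
  if (inherits(density, "enrich_img")) sel <- sel & density$valid
  n <- sum(sel)
  if (n == 0L) stop("mask selects no valid density pixels", call. = FALSE)
  k <- ceiling(pct * n / 100)
  cutoff <- sort(g[sel], decreasing = TRUE)[k]
  sub <- sel & g >= cutoff
  if (sum(sub) < 3L)
    stop("top-percentile subset smaller than 3 px", call. = FALSE)
  out <- list(roi = roi(sub, label = sprintf("top_%g_pct", pct),
                        kind = "custom",
                        provenance = sprintf("density >= %g (top %g%% nearest-rank)",
                                             cutoff, pct)),
              cutoff = cutoff, n_subset = sum(sub), n_mask = n)
  if (!is.null(stack) && !is.null(companion_rd)) {
    out$companion <- pooled_roi_ratio(stack, out$roi, companion_rd)
    out$background_scaled <- ratio_to_scaled(companion_rd$R0)
  }
  out
}

#' Pulse-chase summary table
#'
#' Aggregates per-cell pooled enrichments into a long-format table: per
#' timepoint and compartment, the number of cells and the mean, SD and SE of
#' enrichment — ready for external plotting and standard inference.
#'
#' @param per_cell data.frame with columns \code{cell_id},
#'   \code{timepoint}, \code{compartment}, \code{enrichment}.
#' @return data.frame: timepoint, compartment, n_cells, mean, sd, se
#'   (sd/se NA when a cell is alone in its group).
#' @export
pulse_chase_table <- function(per_cell) {
  req <- c("cell_id", "timepoint", "compartment", "enrichment")
  if (!is.data.frame(per_cell) || !all(req %in% names(per_cell)) ||
      nrow(per_cell) < 1L)
    stop("per_cell must be a data.frame with columns cell_id, timepoint, compartment, enrichment",
         call. = FALSE)
  sp <- split(per_cell,
              list(per_cell$timepoint, per_cell$compartment), drop = TRUE)
  rows <- lapply(sp, function(g) {
    n <- nrow(g)
    s <- if (n > 1L) stats::sd(g$enrichment) else NA_real_
    data.frame(timepoint = g$timepoint[1L], compartment = g$compartment[1L],
               n_cells = n, mean = mean(g$enrichment), sd = s,
               se = if (is.na(s)) NA_real_ else s / sqrt(n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compartment, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Descriptive condition contrast
#'
#' Per-group mean with a t-based confidence interval and the percent change
#' of each group against a named reference group. Purely descriptive:
#' inferential ANOVA and multiple-comparison machinery are deliberately left
#' to standard external routines operating on the exported per-cell values.
#'
#' @param groups named list, condition -> numeric vector of per-cell means.
#' @param reference name of the reference condition (default: first group).
#' @param conf_level confidence level for the per-group CI.
#' @return data.frame: condition, n, mean, sd, ci_lower, ci_upper,
#'   pct_change_vs_reference.
#' @export
condition_contrast <- function(groups, reference = names(groups)[1L],
                               conf_level = 0.95) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)))
    stop("groups must be a named list with at least 2 conditions",
         call. = FALSE)
  if (!reference %in% names(groups))
    stop(sprintf("unknown reference group '%s'", reference), call. = FALSE)
  ref_mean <- mean(groups[[reference]])
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    n <- length(v); mu <- mean(v)
    s <- if (n > 1L) stats::sd(v) else NA_real_
    half <- if (n > 1L) stats::qt(1 - (1 - conf_level) / 2, n - 1L) * s / sqrt(n)
            else NA_real_
    data.frame(condition = g, n = n, mean = mu, sd = s,
               ci_lower = mu - half, ci_upper = mu + half,
               pct_change_vs_reference = 100 * (mu - ref_mean) / ref_mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  out
}

#' Per-image P/S DNA-density proxy grid
#'
#' The 31P/32S ion ratio is a label-free ordinal proxy for DNA density
#' (chromatin is phosphorus-rich and sulfur-poor). No natural background
#' exists for P/S, so the grid is expressed relative to a within-image
#' reference: the cytoplasmic median P/S (or the masked-region median when no
#' cytoplasm ROI is given).
#'
#' @param stack a [mass_stack()] with 31P and 32S channels.
#' @param reference_roi [roi()] whose median P/S serves as the unit
#'   (typically the cytoplasm); NULL uses the whole image median.
#' @param min_denominator minimum 32S counts for a valid pixel.
#' @return an \code{enrich_img} whose values are the P/S ratio relative to
#'   the reference median (100 percent = twice the reference).
#' @export
ps_proxy <- function(stack, reference_roi = NULL, min_denominator = 20) {
  ri <- compute_ratio_image(stack, ratio_definition("31P", "32S", 1, "P_S"),
                            min_denominator)
  sel <- if (is.null(reference_roi)) ri$valid
         else (if (inherits(reference_roi, "roi")) reference_roi$mask
               else reference_roi) & ri$valid
  if (sum(sel) == 0L) stop("no valid reference pixels for P/S", call. = FALSE)
  r0 <- stats::median(ri$ratio[sel])
  if (!is.finite(r0) || r0 <= 0)
    stop("reference median P/S is not positive", call. = FALSE)
  rd <- ratio_definition("31P", "32S", r0, "P_S")
  vals <- matrix(NA_real_, nrow(ri$ratio), ncol(ri$ratio))
  vals[ri$valid] <- enrichment_from_ratio(ri$ratio[ri$valid], r0)
  structure(list(values = vals, valid = ri$valid, ratio_def = rd,
                 min_denominator = min_denominator,
                 pixel_size = if (inherits(stack, "mass_stack"))
                   stack$pixel_size else NA_real_),
            class = "enrich_img")
}
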