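#' Detect top-ranked square hotspot windows
#'
#' Automated hotspot selection: every \code{window x window} square fully
#' inside the search mask (and not touching the exclusion mask) is scored by
#' the pooled isotope ratio of its summed counts; the top \code{top_n} are
#' returned with dense ranks. Under the default \code{disjoint} policy,
#' windows are selected greedily by descending score, skipping any window
#' that overlaps an already accepted one (overlapping windows would otherwise
#' return near-copies of a single maximum); \code{free} permits overlaps.
#' Ties are broken by higher total denominator counts, then by row-major
#' origin order.
#'
#' @param stack a [mass_stack()] or named list of count grids.
#' @param rd a [ratio_definition()].
#' @param window square side in px (default 4).
#' @param top_n number of hotspots requested; fewer are returned if fewer
#'   candidates exist.
#' @param search_mask [roi()] or logical matrix of admissible pixels
#'   (windows must lie fully inside it).
#' @param exclusion_mask optional [roi()] or logical matrix (e.g. the
#'   nucleolar mask); windows intersecting it are discarded.
#' @param overlap_policy \code{"disjoint"} (default) or \code{"free"}.
#' @return data.frame of class \code{hotspot_set}: rank, origin_row,
#'   origin_col (1-based), size_px, window_ratio, window_enrichment,
#'   sum_num, sum_den; attributes carry the ratio definition and window.
#' @export
detect_hotspots <- function(stack, rd, window = 4L, top_n = 20L,
                            search_mask, exclusion_mask = NULL,
                            overlap_policy = c("disjoint", "free")) {
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(inherits(rd, "ratio_def"), window >= 1L, top_n >= 1L)
  chans <- if (inherits(stack, "mass_stack")) stack$channels else stack
  for (sp in c(rd$numerator, rd$denominator))
    if (!sp %in% names(chans))
      stop(sprintf("species '%s' missing from the stack", sp), call. = FALSE)
  num <- chans[[rd$numerator]]; den <- chans[[rd$denominator]]
  mask <- if (inherits(search_mask, "roi")) search_mask$mask else search_mask
  if (sum(mask) == 0L) stop("search mask is empty", call. = FALSE)
  if (window > nrow(num) || window > ncol(num))
    stop("window larger than the image", call. = FALSE)
  excl <- if (is.null(exclusion_mask)) NULL
          else if (inherits(exclusion_mask, "roi")) exclusion_mask$mask
          else exclusion_mask

  w_mask <- window_sums(mask + 0, window)
  ok <- w_mask == window^2
  if (!is.null(excl)) ok <- ok & (window_sums(excl + 0, window) == 0)
  if (!any(ok))
    stop("window larger than the search mask extent: no candidate windows",
         call. = FALSE)
  w_num <- window_sums(num, window); w_den <- window_sums(den, window)
  ok <- ok & w_den > 0
  cand <- which(ok, arr.ind = TRUE)
  score <- w_num[ok] / w_den[ok]
  dsum <- w_den[ok]
  # ties: higher denominator counts, then row-major (row, then col) order
  ord <- order(-score, -dsum, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  score <- score[ord]; dsum <- dsum[ord]; nsum <- w_num[ok][ord]

  keep <- integer(0)
  if (overlap_policy == "free") {
    keep <- seq_len(min(top_n, nrow(cand)))
  } else {
    occupied <- matrix(FALSE, nrow(num), ncol(num))
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1L]; c_ <- cand[i, 2L]
      if (any(occupied[r:(r + window - 1L), c_:(c_ + window - 1L)])) next
      occupied[r:(r + window - 1L), c_:(c_ + window - 1L)] <- TRUE
      keep <- c(keep, i)
      if (length(keep) == top_n) break
    }
  }
  out <- data.frame(rank = seq_along(keep),
                    origin_row = cand[keep, 1L], origin_col = cand[keep, 2L],
                    size_px = window,
                    window_ratio = score[keep],
                    window_enrichment = enrichment_from_ratio(score[keep], rd$R0),
                    sum_num = nsum[keep], sum_den = dsum[keep])
  attr(out, "ratio_def") <- rd
  attr(out, "window") <- window
  attr(out, "overlap_policy") <- overlap_policy
  class(out) <- c("hotspot_set", "data.frame")
  out
}

#' Extract the complementary tracer within each hotspot window
#'
#' The mass channels are acquired in parallel, so every pixel carries both
#' isotope measurements from the same sputtered nanovolume: the complementary
#' label is read from exactly the same window pixels. The nuclear (search
#' region) mean of both tracers is attached as the reference-line value.
#'
#' @param hotspots a [detect_hotspots()] result.
#' @param other_rd [ratio_definition()] of the complementary tracer.
#' @param stack the [mass_stack()].
#' @param reference_roi optional [roi()] (e.g. the nucleus) over which the
#'   reference means are pooled.
#' @return the hotspot_set with \code{complementary_ratio} and
#'   \code{complementary_enrichment} columns; attributes
#'   \code{primary_reference} / \code{complementary_reference} hold pooled
#'   reference enrichments when \code{reference_roi} is given.
#' @export
colocalize_hotspots <- function(hotspots, other_rd, stack,
                                reference_roi = NULL) {
  stopifnot(inherits(hotspots, "hotspot_set"), inherits(other_rd, "ratio_def"))
  chans <- if (inherits(stack, "mass_stack")) stack$channels else stack
  for (sp in c(other_rd$numerator, other_rd$denominator))
    if (!sp %in% names(chans))
      stop(sprintf("complementary species '%s' missing from the stack", sp),
           call. = FALSE)
  num <- chans[[other_rd$numerator]]; den <- chans[[other_rd$denominator]]
  w <- attr(hotspots, "window")
  cr <- ce <- numeric(nrow(hotspots))
  for (i in seq_len(nrow(hotspots))) {
    r <- hotspots$origin_row[i]; c_ <- hotspots$origin_col[i]
    sn <- sum(num[r:(r + w - 1L), c_:(c_ + w - 1L)])
    sd_ <- sum(den[r:(r + w - 1L), c_:(c_ + w - 1L)])
    cr[i] <- if (sd_ > 0) sn / sd_ else NA_real_
    ce[i] <- if (sd_ > 0) enrichment_from_ratio(cr[i], other_rd$R0) else NA_real_
  }
  hotspots$complementary_ratio <- cr
  hotspots$complementary_enrichment <- ce
  if (!is.null(reference_roi)) {
    attr(hotspots, "primary_reference") <-
      pooled_roi_ratio(stack, reference_roi, attr(hotspots, "ratio_def"))$enrichment
    attr(hotspots, "complementary_reference") <-
      pooled_roi_ratio(stack, reference_roi, other_rd)$enrichment
  }
  attr(hotspots, "complementary_ratio_def") <- other_rd
  hotspots
}

#' Overlay hotspot outlines on a rendered image
#'
#' Draws square outlines at each hotspot window on an RGB render (or a
#' grayscale matrix, which is expanded to RGB). A pure view: the input image
#' is copied, never modified.
#'
#' @param hotspots a [detect_hotspots()] result.
#' @param base_image RGB array (rows x cols x 3, values in [0,1]) or a
#'   numeric matrix (auto-normalized grayscale).
#' @param color length-3 RGB in [0,1] for the outline (default green).
#' @return RGB array with outlines drawn.
#' @export
hotspot_overlay <- function(hotspots, base_image, color = c(0, 1, 0)) {
  if (is.matrix(base_image)) {
    g <- base_image / max(base_image, 1e-12)
    base_image <- array(rep(g, 3L), c(dim(g), 3L))
  }
  out <- base_image
  if (nrow(hotspots) == 0L) return(out)
  w <- attr(hotspots, "window")
  for (i in seq_len(nrow(hotspots))) {
    r <- hotspots$origin_row[i]; c_ <- hotspots$origin_col[i]
    rr <- r:(r + w - 1L); cc <- c_:(c_ + w - 1L)
    for (k in 1:3) {
      out[rr[1L], cc, k] <- color[k]; out[rr[w], cc, k] <- color[k]
      out[rr, cc[1L], k] <- color[k]; out[rr, cc[w], k] <- color[k]
    }
  }
  out
}

#' Export a hotspot table as TSV
#'
#' Writes rank, 0-based origin coordinates, window size and the primary /
#' complementary enrichments, with the reference means when present.
#'
#' @param hotspots a hotspot_set.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_hotspot_table <- function(hotspots, path) {
  df <- data.frame(rank = hotspots$rank,
                   origin_row = hotspots$origin_row - 1L,
                   origin_col = hotspots$origin_col - 1L,
                   size_px = hotspots$size_px,
                   primary_enrichment_pct = hotspots$window_enrichment)
  if (!is.null(hotspots$complementary_enrichment))
    df$complementary_enrichment_pct <- hotspots$complementary_enrichment
  ref <- attr(hotspots, "primary_reference")
  if (!is.null(ref)) df$nuclear_mean_pct <- ref
  cref <- attr(hotspots, "complementary_reference")
  if (!is.null(cref)) df$complementary_nuclear_mean_pct <- cref
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
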