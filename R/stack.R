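#' Multi-species ion-count image stack
#'
#' The universal input container: one 2D non-negative integer count grid per
#' detected ion species (e.g. \code{"12C14N"}, \code{"12C15N"}, \code{"31P"}),
#' all sharing one raster shape, plus the pixel size and free-form provenance
#' metadata.
#'
#' @param channels named list of non-negative integer matrices, one per ion
#'   species; all must share one shape.
#' @param pixel_size pixel edge length in nanometres (> 0).
#' @param metadata free-form named list of provenance information.
#' @return an object of class \code{mass_stack}.
#' @examples
#' s <- mass_stack(list(`12C14N` = matrix(100L, 8, 8),
#'                      `12C15N` = matrix(1L, 8, 8)), pixel_size = 100)
#' dim(s)
#' @export
mass_stack <- function(channels, pixel_size, metadata = list()) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a non-empty named list of matrices", call. = FALSE)
  if (anyDuplicated(names(channels)))
    stop("duplicate species names in channels", call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1L))))
    stop("every channel must be a matrix", call. = FALSE)
  if (length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
    stop("all channel grids must share one shape", call. = FALSE)
  channels <- lapply(channels, function(ch) {
    storage.mode(ch) <- "double"
    as_integerish(ch, "channel counts")
  })
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (nm)", call. = FALSE)
  structure(list(channels = channels, pixel_size = pixel_size,
                 metadata = metadata),
            class = "mass_stack")
}

#' @export
dim.mass_stack <- function(x) dim(x$channels[[1L]])

#' @export
print.mass_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("mass_stack: %d x %d px (%.0f nm/px), %d species\n",
              d[1L], d[2L], x$pixel_size, length(x$channels)))
  for (nm in names(x$channels))
    cat(sprintf("  %-8s total %s counts\n", nm,
                format(sum(x$channels[[nm]]), big.mark = ",")))
  invisible(x)
}

#' Extract a species channel from a stack
#'
#' @param stack a \code{mass_stack}.
#' @param species species name; must be present.
#' @return the count matrix for that species.
#' @export
stack_channel <- function(stack, species) {
  stopifnot(inherits(stack, "mass_stack"))
  if (!species %in% names(stack$channels))
    stop(sprintf("species '%s' not present in stack (have: %s)", species,
                 paste(names(stack$channels), collapse = ", ")), call. = FALSE)
  stack$channels[[species]]
}

#' Save / load a mass stack as multi-page TIFF + JSON sidecar
#'
#' Counts are stored as 16-bit integer TIFF pages (exact round-trip for counts
#' up to 65535); the JSON sidecar records species names, pixel size (nm) and
#' metadata. \code{load_stack} validates that the sidecar and TIFF agree
#' (page count, shapes) and that all pages hold non-negative integers.
#'
#' @param stack a \code{mass_stack}.
#' @param path path of the TIFF file; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @return \code{save_stack}: the path, invisibly. \code{load_stack}: a
#'   \code{mass_stack}.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "mass_stack"))
  mx <- max(vapply(stack$channels, max, numeric(1L)))
  if (mx > 65535)
    stop("counts exceed 65535; 16-bit TIFF storage cannot represent them",
         call. = FALSE)
  pages <- lapply(stack$channels, function(ch) ch / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE,
                  compression = "none")
  sidecar <- list(species = names(stack$channels),
                  pixel_size_nm = stack$pixel_size,
                  shape = dim(stack),
                  metadata = stack$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_stack
#' @export
load_stack <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop(sprintf("missing JSON sidecar '%s'", sidecar_path), call. = FALSE)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(sc$species))
    stop(sprintf("sidecar lists %d species but TIFF has %d pages",
                 length(sc$species), length(pages)), call. = FALSE)
  pages <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample") %||% 16L
    v <- as.vector(p) * (2^bits - 1)  # undo the [0,1] normalization
    if (any(v < 0) || any(abs(v - round(v)) > 1e-3))
      stop("TIFF page holds negative or non-integer values; counts must be non-negative integers",
           call. = FALSE)
    matrix(round(v), nrow(p), ncol(p))
  })
  names(pages) <- sc$species
  mass_stack(pages, pixel_size = sc$pixel_size_nm,
             metadata = as.list(sc$metadata %||% list()))
}
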