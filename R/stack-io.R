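#' Write / read two-channel stacks as TIFF with a JSON sidecar
#'
#' Each channel is written as a multi-page 32-bit float TIFF
#' (`<prefix>_<channel>.tif`, one page per z slice) together with a JSON
#' sidecar `<prefix>.json` recording channel names, voxel spacing, the
#' base-plane index, an intensity scale (pages are stored divided by it)
#' and any metadata such as ground-truth parameters and seeds.
#'
#' @param stack A [stack3d()].
#' @param prefix Output path prefix (no extension).
#' @return `write_stack_tiff` returns the sidecar path invisibly;
#'   `read_stack_tiff` returns a [stack3d()].
#' @export
write_stack_tiff <- function(stack, prefix) {
  stopifnot(inherits(stack, "stack3d"))
  scale <- max(1, max(vapply(stack$channels, max, numeric(1))))
  files <- character(0)
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]] / scale
    pages <- lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ])
    f <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, f, bits.per.sample = 32L)
    files <- c(files, basename(f))
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(channels = names(stack$channels), files = files,
         spacing_um = stack$spacing, base_index = stack$base_index,
         intensity_scale = scale, meta = stack$meta),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(sidecar)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(prefix) {
  sidecar <- if (grepl("\\.json$", prefix)) prefix else paste0(prefix, ".json")
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dirn <- dirname(sidecar)
  chans <- list()
  for (i in seq_along(side$channels)) {
    pages <- tiff::readTIFF(file.path(dirn, side$files[i]), all = TRUE)
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (j in seq_along(pages)) arr[j, , ] <- pages[[j]]
    chans[[side$channels[i]]] <- arr * side$intensity_scale
  }
  stack3d(chans, spacing = side$spacing_um,
          base_index = side$base_index,
          meta = if (is.null(side$meta)) list() else side$meta)
}
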