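# TIFF round-trip for z-stacks and multi-channel stacks.  Intensities are
# stored as 32-bit float pages scaled by 1/INTENSITY_SCALE so arbitrary-unit
# signals fit the [0, 1] range the format expects.
INTENSITY_SCALE <- 1000

#' Write / read a multi-page TIFF stack
#'
#' `write_stack_tiff()` serialises a list of 3D arrays (one per channel or
#' time frame, dim `c(nz, ny, nx)`) as a multi-page float TIFF, pages
#' ordered frame-major then z.  `read_stack_tiff()` reverses it.
#'
#' @param arrays List of 3D numeric arrays of identical dimensions.
#' @param path Output file.
#' @return `read_stack_tiff()` returns the list of arrays; `n_per_stack`
#'   pages are grouped per array.
#' @keywords internal
#' @export
write_stack_tiff <- function(arrays, path) {
  stopifnot(is.list(arrays), length(arrays) >= 1)
  pages <- list()
  for (a in arrays) {
    stopifnot(length(dim(a)) == 3)
    for (z in seq_len(dim(a)[1]))
      pages[[length(pages) + 1]] <- pmin(a[z, , ] / INTENSITY_SCALE, 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param n_arrays Number of arrays the pages divide into.
#' @export
read_stack_tiff <- function(path, n_arrays) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) %% n_arrays == 0)
  nz <- length(pages) %/% n_arrays
  lapply(seq_len(n_arrays), function(i) {
    sl <- pages[((i - 1) * nz + 1):(i * nz)]
    a <- array(0, c(nz, nrow(sl[[1]]), ncol(sl[[1]])))
    for (z in seq_len(nz)) a[z, , ] <- sl[[z]] * INTENSITY_SCALE
    a
  })
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an experiment manifest written by [simulate_experiment()]
#'
#' @param path Path to `manifest.json`.
#' @return The manifest as a nested list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
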