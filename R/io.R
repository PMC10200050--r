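#' Read a leaf image
#'
#' Reads 8-bit RGB (or grayscale) PNG, TIFF or JPEG into a numeric array
#' `height x width x 3` with values in `[0, 1]`. Grayscale input is
#' expanded to three identical channels; an alpha channel is dropped.
#'
#' @param path Image file path; format is taken from the extension.
#' @return Numeric array `height x width x 3`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format '%s' (use png/tiff/jpeg)", ext))
  )
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  img
}

#' @rdname read_image
#' @param image Numeric array `height x width x 3` in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  image[image < 0] <- 0
  image[image > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(image, path),
    stop(sprintf("unsupported image format '%s' (use png/tiff/jpeg)", ext))
  )
  invisible(path)
}

#' Read or write a flat key/value pipeline config file
#'
#' The config file holds one `key = value` pair per line (`#` comments
#' allowed), mirroring the fields of [pipeline_config()].
#'
#' @param path File path.
#' @return `read_config()` returns a [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  num <- setdiff(known, "edge_policy")
  vals[names(vals) %in% num] <- lapply(vals[names(vals) %in% num], as.numeric)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, "")), path)
  invisible(path)
}
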