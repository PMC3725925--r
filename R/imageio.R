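# Readers return intensities on the 0-255 scale as numeric matrices
# (grayscale) or h x w x 3 arrays (RGB), rows = image rows. Coordinates are
# row-major with pixel-center convention throughout the package.

readPNM <- function(path) {
  # P2/P3 (ASCII) and P5/P6 (binary) portable any-maps; STARE ships PPM.
  con <- file(path, "rb")
  on.exit(close(con))
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of PNM file: ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  magic <- readToken()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path)
  w <- as.integer(readToken())
  h <- as.integer(readToken())
  maxval <- as.integer(readToken())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("truncated PNM file: ", path)
  vals <- vals * (255 / maxval)
  if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, dim = c(h, w, 3L))
    for (k in 1:3)
      a[, , k] <- matrix(vals[seq(k, n, by = 3L)], h, w, byrow = TRUE)
    a
  }
}

#' Read an image file as an intensity array
#'
#' Supports PNG, TIFF and PPM/PGM (the native formats of the DRIVE and
#' STARE databases, except DRIVE's GIF masks, for which no decoder is
#' available -- convert those to PNG first). Values are returned on the
#' 0--255 scale; grayscale gives a matrix, RGB an h x w x 3 array.
#'
#' @param path file path.
#' @return Numeric matrix or 3-d array.
#' @export
readImageMatrix <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    ppm = ,
    pgm = readPNM(path),
    gif = stop("GIF decoding is not supported; convert '", path,
               "' to PNG (e.g. `convert mask.gif mask.png`)"),
    stop("unsupported image format '.", ext, "': ", path))
  if (length(dim(a)) == 3L && dim(a)[3] > 3L) a <- a[, , 1:3]  # drop alpha
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1L]
  a
}

#' Write a binary map as an 8-bit PNG
#'
#' TRUE pixels become 255, FALSE become 0, so the file round-trips exactly
#' through [readImageMatrix()] and a > 127 threshold.
#'
#' @param mask logical matrix.
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
writeBinaryImage <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

extractChannel <- function(a, channel = c("green", "red", "blue", "gray")) {
  channel <- match.arg(channel)
  if (is.matrix(a)) {
    if (channel != "gray")
      message("grayscale input: '", channel, "' channel rule ignored")
    return(a)
  }
  switch(channel,
    red = a[, , 1L],
    green = a[, , 2L],
    blue = a[, , 3L],
    gray = 0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L])
}

#' Load a retinal sample from image files
#'
#' Reads a fundus image plus optional FOV mask and manual vessel map,
#' reduces RGB input to a working channel (the green channel by default,
#' where vessel contrast is highest), and binarizes the 8-bit masks at
#' > 127. When no FOV file is given, the mask is estimated from the image
#' with [estimateFov()].
#'
#' @param imagePath path of the fundus image.
#' @param fovPath optional FOV mask image path.
#' @param truthPath optional manual vessel map path.
#' @param channel working channel rule for RGB input.
#' @param sampleId identifier; defaults to the image file name.
#' @return A [RetinalSample-class].
#' @export
loadSample <- function(imagePath, fovPath = NULL, truthPath = NULL,
                       channel = "green", sampleId = NULL) {
  img <- extractChannel(readImageMatrix(imagePath), channel)
  if (is.null(sampleId))
    sampleId <- tools::file_path_sans_ext(basename(imagePath))
  binarize <- function(path, what) {
    m <- readImageMatrix(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    if (!identical(dim(m), dim(img)))
      stop(what, " shape ", paste(dim(m), collapse = "x"),
           " does not match image shape ", paste(dim(img), collapse = "x"))
    m > 127
  }
  fov <- if (is.null(fovPath)) estimateFov(img) else binarize(fovPath, "fov")
  truth <- if (is.null(truthPath)) NULL else binarize(truthPath, "truth")
  retinalSample(img, fov = fov, truth = truth, sampleId = sampleId)
}

#' Estimate the field-of-view mask from image brightness
#'
#' The retinal FOV is the bright disk of a fundus photograph. The estimate
#' is the largest connected component of pixels brighter than
#' `thresholdFraction` times the maximum intensity, morphologically closed
#' (disk of radius 5) and hole-filled.
#'
#' @param image intensity matrix or [RetinalSample-class].
#' @param thresholdFraction brightness threshold as a fraction of the
#'   maximum (default 0.08).
#' @return Logical FOV mask.
#' @export
estimateFov <- function(image, thresholdFraction = 0.08) {
  image <- asIntensityMatrix(image)
  bright <- image > thresholdFraction * max(image)
  if (!any(bright))
    stop("FOV estimation failed: no pixel above the brightness threshold; ",
         "supply an explicit mask file")
  lab <- EBImage::bwlabel(bright)
  counts <- tabulate(lab[lab > 0])
  mask <- lab == which.max(counts)
  brush <- EBImage::makeBrush(11L, shape = "disc")
  mask <- EBImage::fillHull(EBImage::closing(mask, brush)) > 0
  matrix(as.logical(mask), nrow(image), ncol(image))
}

#' Discover samples in DRIVE- or STARE-style directories
#'
#' DRIVE layout: `images/`, `mask/` and `1st_manual/` (or `2nd_manual/`)
#' subdirectories whose files share a leading numeric sample id. STARE
#' layout: flat files `imNNNN.*` with manual maps `imNNNN.ah.*` /
#' `imNNNN.vk.*`; STARE has no FOV masks, so the fov column is NA and
#' loading falls back to [estimateFov()]. File extensions are not assumed.
#'
#' @param root database root directory.
#' @param layout "drive" or "stare".
#' @param annotator which manual annotation to use: "1st"/"2nd" for DRIVE,
#'   "ah"/"vk" for STARE.
#' @return data.frame with columns id, image, fov, truth (paths or NA).
#' @export
discoverSamples <- function(root, layout = c("drive", "stare"),
                            annotator = NULL) {
  layout <- match.arg(layout)
  if (layout == "drive") {
    annotator <- if (is.null(annotator)) "1st" else annotator
    imgs <- list.files(file.path(root, "images"), full.names = TRUE)
    ids <- sub("^([0-9]+).*$", "\\1", basename(imgs))
    findFor <- function(dir, id) {
      f <- list.files(file.path(root, dir), full.names = TRUE,
                      pattern = paste0("^", id, "[^0-9]"))
      if (length(f)) f[1] else NA_character_
    }
    data.frame(id = ids, image = imgs,
               fov = vapply(ids, findFor, "", dir = "mask"),
               truth = vapply(ids, findFor, "",
                              dir = paste0(annotator, "_manual")),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    annotator <- if (is.null(annotator)) "ah" else annotator
    all <- list.files(root, full.names = TRUE)
    base <- basename(all)
    imgs <- all[grepl("^im[0-9]+\\.(ppm|png|tif|tiff|pgm)$", base)]
    ids <- sub("^(im[0-9]+)\\..*$", "\\1", basename(imgs))
    truth <- vapply(ids, function(id) {
      f <- all[grepl(paste0("^", id, "\\.", annotator, "\\."), base)]
      if (length(f)) f[1] else NA_character_
    }, "")
    data.frame(id = ids, image = imgs, fov = NA_character_, truth = truth,
               row.names = NULL, stringsAsFactors = FALSE)
  }
}
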