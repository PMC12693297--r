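# Texture layer: RDG diagram image -> quantized luminance grid -> 8x8
# gray-level co-occurrence matrix -> 64-element feature vector (MLP input).

#' Load a raster image
#'
#' Reads a PNG (via the png package) or, when the EBImage package is
#' available, other raster formats such as JPEG. Grayscale images are
#' promoted to three identical channels; an alpha channel is dropped.
#'
#' @param path Path to the image file.
#' @return An integer array `height x width x 3` with values in 0..255.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- try(png::readPNG(path), silent = TRUE)
    if (inherits(img, "try-error")) stop("cannot read PNG: ", path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("non-PNG image '", path, "' needs the EBImage package")
    }
    e <- try(EBImage::readImage(path), silent = TRUE)
    if (inherits(e, "try-error")) stop("cannot read image: ", path)
    a <- as.array(e)              # EBImage stores x,y[,c]
    img <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  }
  if (length(dim(img)) == 2L) {
    img <- array(img, c(dim(img), 3L))
  } else if (dim(img)[3] == 2L) {          # gray + alpha
    img <- array(img[, , 1L], c(dim(img)[1:2], 3L))
  } else if (dim(img)[3] >= 4L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] == 1L) {
    img <- array(img[, , 1L], c(dim(img)[1:2], 3L))
  }
  storage.mode(img) <- "double"
  array(as.integer(round(img * 255)), dim(img))
}

# ITU-R BT.601 luma from an H x W x 3 array in 0..255.
.luminance <- function(img) {
  round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Quantize an image to discrete gray levels
#'
#' Computes luminance (0.299 R + 0.587 G + 0.114 B, rounded) and bins it
#' linearly into `levels` equal-width bins over \[0, 255\].
#'
#' @param image `H x W x 3` array in 0..255 (see [load_image()]), or an
#'   `H x W` luminance matrix.
#' @param levels Number of gray levels, at least 2. Default 8, giving the
#'   8 x 8 co-occurrence matrices used by the texture branch.
#' @return An integer matrix of level indices in `0..(levels-1)` with
#'   attribute `levels`.
#' @export
quantize <- function(image, levels = 8L) {
  if (levels < 2L) stop("'levels' must be >= 2")
  lum <- if (length(dim(image)) == 3L) .luminance(image) else image
  q <- pmin(floor(lum * levels / 256), levels - 1L)
  storage.mode(q) <- "integer"
  attr(q, "levels") <- as.integer(levels)
  q
}

#' Gray-level co-occurrence matrix
#'
#' Counts how often gray-level pairs co-occur at the given pixel
#' displacements, accumulated over all offsets. Offsets are `(dy, dx)` in
#' matrix (row, column) convention. The default four unit offsets —
#' horizontal, vertical and both diagonals — with symmetric counting give
#' the standard rotation-robust texture descriptor.
#'
#' @param q Quantized grid from [quantize()].
#' @param offsets List of `c(dy, dx)` integer displacements, each non-zero
#'   and smaller than the grid extent.
#' @param symmetric Count each pair in both directions? Default `TRUE`.
#' @param normalize Divide by the total count so entries sum to 1? Default
#'   `TRUE`.
#' @param mask_background Exclude pixel pairs where both pixels fall in the
#'   top luminance bin (the white page background of scatter-style RDG
#'   plots)? Default `FALSE`.
#' @return A `levels x levels` matrix of class `"glcm"` with attributes
#'   `normalized`, `symmetric`, `offsets`, `levels`.
#' @export
glcm <- function(q,
                 offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)),
                 symmetric = TRUE, normalize = TRUE,
                 mask_background = FALSE) {
  if (is.null(dim(q)) || any(dim(q) == 0L)) stop("empty grid")
  levels <- attr(q, "levels")
  if (is.null(levels)) levels <- max(q) + 1L
  h <- nrow(q); w <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    dy <- off[[1]]; dx <- off[[2]]
    if (dy == 0L && dx == 0L) stop("offset (0,0) is not allowed")
    if (abs(dy) >= h || abs(dx) >= w) {
      stop("offset (", dy, ",", dx, ") exceeds grid extent ", h, "x", w)
    }
    rows <- seq_len(h - abs(dy))
    cols <- seq_len(w - abs(dx))
    r1 <- if (dy >= 0L) rows else rows + abs(dy)
    c1 <- if (dx >= 0L) cols else cols + abs(dx)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dy, c1 + dx, drop = FALSE]
    keep <- if (mask_background) !(a == levels - 1L & b == levels - 1L) else TRUE
    idx <- (a + levels * b + 1L)[keep]      # level pair -> linear cell
    tab <- tabulate(idx, nbins = levels * levels)
    counts <- counts + matrix(tab, levels, levels)
  }
  if (symmetric) counts <- counts + t(counts)
  if (normalize) {
    tot <- sum(counts)
    if (tot > 0) counts <- counts / tot
  }
  structure(counts, class = c("glcm", "matrix"),
            normalized = normalize, symmetric = symmetric,
            offsets = offsets, levels = as.integer(levels))
}

#' @export
print.glcm <- function(x, digits = 4, ...) {
  cat("<glcm> ", attr(x, "levels"), " levels",
      if (isTRUE(attr(x, "normalized"))) ", normalized", "\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Flatten a normalized GLCM to a texture feature vector
#'
#' Row-major flattening of the `levels x levels` normalized co-occurrence
#' matrix; with the default 8 levels this is the 64-vector consumed by the
#' perceptron branch of the Siamese model.
#'
#' @param g Normalized GLCM from [glcm()].
#' @return Numeric vector of length `levels^2` summing to 1.
#' @export
glcm_feature <- function(g) {
  if (!isTRUE(attr(g, "normalized"))) {
    stop("GLCM must be normalized (call glcm(..., normalize = TRUE))")
  }
  as.vector(t(unclass(g)))
}

#' Full image-to-feature texture pipeline
#'
#' Convenience wrapper: load an RDG image, quantize to `levels` grays, and
#' return the flattened normalized GLCM feature vector.
#'
#' @param path Image file path.
#' @param levels Gray levels (default 8).
#' @param ... Passed to [glcm()].
#' @return Numeric feature vector of length `levels^2`.
#' @export
rdg_texture_feature <- function(path, levels = 8L, ...) {
  glcm_feature(glcm(quantize(load_image(path), levels), ...))
}
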