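# Interpretability: Grad-CAM over the CNN branch, gradient saliency over
# the GLCM/MLP branch, and 2D embedding projections.
#
# The model is a metric learner, not a classifier, so the scalar driving
# both maps is the negative squared embedding distance to a reference
# embedding: high-attention regions are those pulling the sample toward the
# reference in the shared space.

.interpret_grads <- function(model, sample, reference) {
  model <- .as_model(model)
  .check_mep(model, sample$mep)
  if (length(reference) != model$config$embedding_dim) {
    stop("reference embedding has wrong dimension")
  }
  f <- .embed_fwd(model$params, model$config, sample$mep,
                  as.numeric(sample$glcm))
  de <- -2 * (f$e - reference)       # d/de of -||e - reference||^2
  bw <- .embed_bwd(model$params, model$config, f$cache, de)
  list(fwd = f, bwd = bw)
}

.minmax01 <- function(x, what) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) {
    if (hi == 0 && lo == 0) {
      warning(what, " gradients are identically zero; returning all-zero map")
      return(x * 0)
    }
    return(x * 0)
  }
  (x - lo) / (hi - lo)
}

#' Grad-CAM attention heatmap over the MEP branch
#'
#' Computes the gradient of the similarity objective (negative squared
#' distance between the sample's embedding and `reference`) with respect to
#' the last convolutional block's ReLU activation map, channel-averages the
#' gradients into weights, forms the ReLU-rectified weighted activation
#' map, upsamples it to the input resolution, and min-max normalizes to
#' \[0, 1\] (max exactly 1 on non-degenerate inputs).
#'
#' @param model A `"siamese_fit"` or `"siamese_model"`.
#' @param sample Multimodal sample (`list(mep, glcm)`).
#' @param reference Reference (anchor) embedding vector.
#' @return `input_size x input_size` matrix of attention values in \[0, 1\].
#' @export
gradcam <- function(model, sample, reference) {
  g <- .interpret_grads(model, sample, reference)
  A <- g$fwd$cache$last_relu               # Hc x Wc x C activations
  dA <- g$bwd$d_last_relu
  alpha <- colMeans(matrix(dA, prod(dim(dA)[1:2]), dim(dA)[3]))
  d <- dim(A)
  cam <- matrix(matrix(A, prod(d[1:2]), d[3]) %*% alpha, d[1], d[2])
  cam <- pmax(cam, 0)
  size <- .as_model(model)$config$input_size
  up <- .resize_bilinear(array(cam, c(d[1], d[2], 1L)), size, size)[, , 1]
  .minmax01(up, "Grad-CAM")
}

#' Gradient saliency over the GLCM texture input
#'
#' Absolute gradient of the similarity objective with respect to the 64
#' GLCM entries, min-max normalized to \[0, 1\].
#'
#' @inheritParams gradcam
#' @return Numeric vector of length 64 in \[0, 1\] (attribute `"raw"` holds
#'   the signed gradient).
#' @export
glcm_saliency <- function(model, sample, reference) {
  g <- .interpret_grads(model, sample, reference)
  raw <- g$bwd$dglcm
  s <- .minmax01(abs(raw), "saliency")
  attr(s, "raw") <- raw
  s
}

#' Project embeddings to 2D for visualization
#'
#' Principal-axis (PCA) projection by default, with a deterministic sign
#' convention so identical inputs always give identical layouts; `"mds"`
#' uses classical multidimensional scaling.
#'
#' @param embeddings Matrix with one embedding per row (>= 3 rows).
#' @param method `"pca"` or `"mds"`.
#' @param seed Integer seed (kept for interface stability; both built-in
#'   methods are deterministic).
#' @return `n x 2` coordinate matrix with the input rownames.
#' @export
project_embeddings <- function(embeddings, method = c("pca", "mds"),
                               seed = 1L) {
  method <- match.arg(method)
  e <- as.matrix(embeddings)
  if (nrow(e) < 3L) stop("need at least 3 embeddings to project")
  xy <- .with_seed(seed, {
    if (method == "pca") {
      ctr <- scale(e, center = TRUE, scale = FALSE)
      sv <- svd(ctr, nu = 2, nv = 2)
      u <- sv$u %*% diag(sv$d[1:2], 2)
      # fix sign: largest-magnitude coordinate of each axis is positive
      for (j in 1:2) {
        k <- which.max(abs(u[, j]))
        if (u[k, j] < 0) u[, j] <- -u[, j]
      }
      u
    } else {
      stats::cmdscale(stats::dist(e), k = 2)
    }
  })
  rownames(xy) <- rownames(e)
  colnames(xy) <- c("x", "y")
  xy
}

# Map [0,1] attention values through a blue->cyan->yellow->red ramp.
.heat_colors <- function(h) {
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  ramp(as.vector(h)) / 255
}

#' Render a heatmap overlay on an image
#'
#' Alpha-blends an attention heatmap (its own normalized 0-1 colorscale,
#' independent of the underlying image's colors) over a raster image and
#' writes a PNG.
#'
#' @param img `H x W x 3` array in 0..255 (see [load_image()]).
#' @param heat Matrix of attention values in \[0, 1\]; resized to the image
#'   if needed. A length-64 saliency vector is accepted and reshaped 8x8.
#' @param file Output PNG path.
#' @param alpha Heatmap opacity in \[0, 1\] (default 0.45).
#' @return The output path, invisibly.
#' @export
overlay_heatmap <- function(img, heat, file, alpha = 0.45) {
  if (is.null(dim(heat))) {
    if (length(heat) != 64L) stop("'heat' must be a matrix or a 64-vector")
    heat <- matrix(heat, 8, 8, byrow = TRUE)
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  hm <- .resize_bilinear(array(heat, c(dim(heat), 1L)), h, w)[, , 1]
  hm <- pmin(pmax(hm, 0), 1)
  cols <- .heat_colors(hm)
  out <- array(0, c(h, w, 3))
  for (c in 1:3) {
    out[, , c] <- (1 - alpha) * img[, , c] / 255 +
      alpha * matrix(cols[, c], h, w)
  }
  png::writePNG(out, file)
  invisible(file)
}
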