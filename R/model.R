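# The two-branch Siamese model: CNN over MEP images, MLP over GLCM texture
# vectors, concatenation + projection into a shared embedding space.
# Similarity between compounds is reported as inverse embedding distance
# 1/(1 + d).

#' Construct an untrained Siamese similarity model
#'
#' The upper branch is a small convolutional network over the MEP image
#' (conv-ReLU-maxpool blocks followed by global average pooling); the lower
#' branch is a multilayer perceptron over the 64-element GLCM texture
#' vector. Both feature vectors are concatenated and projected into a shared
#' embedding space of dimension `embedding_dim`, trained with a triplet
#' loss (see [fit_siamese()]).
#'
#' @param embedding_dim Dimension of the shared embedding (default 128).
#' @param conv_filters Filters per conv block (default `c(32, 64, 128)`);
#'   each block is conv (3x3, 'same') -> ReLU -> 2x2 max-pool.
#' @param kernel_size Odd conv kernel size (default 3).
#' @param mlp_hidden Layer sizes of the texture MLP after its 64-d input
#'   (default `c(64, 32)`, all ReLU).
#' @param projector_hidden Hidden width of the fusion projector
#'   (default 128).
#' @param input_size Square MEP input resolution in pixels (default 64);
#'   must be divisible by `2^length(conv_filters)`.
#' @param margin Triplet-loss margin, > 0 (default 1).
#' @param normalize_embeddings L2-normalize embeddings? Default `FALSE`:
#'   similarity scores 1/(1+d) over unnormalized embeddings span the full
#'   (0, 1] range, while unit-norm embeddings would compress distances
#'   below ~2.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `"siamese_model"`: list with `config` and
#'   `params` (named list of weight arrays).
#' @export
siamese_model <- function(embedding_dim = 128L, conv_filters = c(32L, 64L, 128L),
                          kernel_size = 3L, mlp_hidden = c(64L, 32L),
                          projector_hidden = 128L, input_size = 64L,
                          margin = 1, normalize_embeddings = FALSE,
                          seed = 1L) {
  if (margin <= 0) stop("'margin' must be > 0")
  if (embedding_dim < 1 || any(conv_filters < 1) || any(mlp_hidden < 1) ||
      projector_hidden < 1) stop("all layer sizes must be positive")
  if (kernel_size %% 2L != 1L) stop("'kernel_size' must be odd")
  if (input_size %% (2L^length(conv_filters)) != 0L) {
    stop("'input_size' must be divisible by 2^", length(conv_filters))
  }
  cfg <- list(embedding_dim = as.integer(embedding_dim),
              conv_filters = as.integer(conv_filters),
              kernel_size = as.integer(kernel_size),
              mlp_hidden = as.integer(mlp_hidden),
              projector_hidden = as.integer(projector_hidden),
              input_size = as.integer(input_size),
              margin = margin,
              normalize_embeddings = isTRUE(normalize_embeddings),
              seed = as.integer(seed))
  structure(list(config = cfg, params = .init_params(cfg)),
            class = "siamese_model")
}

#' @export
print.siamese_model <- function(x, ...) {
  cfg <- x$config
  cat("Siamese multimodal similarity model (untrained weights unless fitted)\n")
  cat("  CNN branch : input ", cfg$input_size, "x", cfg$input_size,
      "x3, filters ", paste(cfg$conv_filters, collapse = "-"), "\n", sep = "")
  cat("  MLP branch : 64 -> ", paste(cfg$mlp_hidden, collapse = " -> "),
      "\n", sep = "")
  cat("  embedding  : ", cfg$embedding_dim, "d",
      if (cfg$normalize_embeddings) " (L2-normalized)", "\n", sep = "")
  cat("  margin     : ", cfg$margin, "\n", sep = "")
  invisible(x)
}

.check_mep <- function(model, mep) {
  s <- model$config$input_size
  if (!is.array(mep) || length(dim(mep)) != 3L ||
      !all(dim(mep) == c(s, s, 3L))) {
    stop("MEP input must be a ", s, "x", s, "x3 array in [0,1]")
  }
  invisible(TRUE)
}

#' CNN branch: visual features from an MEP image
#'
#' @param model A [siamese_model()].
#' @param mep Preprocessed image array `input_size x input_size x 3`,
#'   values in \[0, 1\] (see [preprocess_mep()]).
#' @return Numeric visual feature vector (length = last conv filter count).
#' @export
cnn_branch <- function(model, mep) {
  .check_mep(model, mep)
  p <- model$params; cfg <- model$config
  x <- mep
  for (i in seq_along(cfg$conv_filters)) {
    x <- .pool2_fwd(pmax(.conv_fwd(x, p[[paste0("conv", i, "_W")]],
                                   p[[paste0("conv", i, "_b")]])$out, 0))$out
  }
  colMeans(matrix(x, prod(dim(x)[1:2]), dim(x)[3]))
}

#' MLP branch: texture features from a GLCM vector
#'
#' @param model A [siamese_model()].
#' @param glcmv Length-64 GLCM feature vector (see [glcm_feature()]).
#' @return Numeric texture feature vector (length = last MLP layer size).
#' @export
mlp_branch <- function(model, glcmv) {
  if (length(glcmv) != 64L) {
    stop("GLCM feature vector must have length 64, got ", length(glcmv))
  }
  p <- model$params; cfg <- model$config
  h <- as.numeric(glcmv)
  for (i in seq_along(cfg$mlp_hidden)) {
    h <- pmax(.dense_fwd(h, p[[paste0("mlp", i, "_W")]],
                         p[[paste0("mlp", i, "_b")]]), 0)
  }
  h
}

#' Fuse branch features and project into the shared embedding space
#'
#' Concatenates the visual and texture feature vectors and applies the
#' projection layers (hidden ReLU layer, then linear map to
#' `embedding_dim`), with optional L2 normalization.
#'
#' @param model A [siamese_model()].
#' @param visual Visual feature vector from [cnn_branch()].
#' @param texture Texture feature vector from [mlp_branch()].
#' @return Embedding vector of length `embedding_dim`.
#' @export
fuse_project <- function(model, visual, texture) {
  p <- model$params
  fuse_in <- nrow(p$proj1_W)
  if (length(visual) + length(texture) != fuse_in) {
    stop("visual+texture length must be ", fuse_in)
  }
  h <- pmax(.dense_fwd(c(visual, texture), p$proj1_W, p$proj1_b), 0)
  e <- .dense_fwd(h, p$proj2_W, p$proj2_b)
  if (model$config$normalize_embeddings) {
    nrm <- sqrt(sum(e^2))
    if (nrm > 0) e <- e / nrm
  }
  e
}

#' Embed multimodal samples
#'
#' @param model A [siamese_model()] or [fit_siamese()] result.
#' @param samples A single sample (list with elements `mep` and `glcm`) or
#'   a named list of such samples (see [load_samples()]).
#' @return A matrix of embeddings, one row per sample.
#' @export
embed_samples <- function(model, samples) {
  model <- .as_model(model)
  if (!is.null(samples$mep)) samples <- list(samples)
  e <- t(vapply(samples, function(s) {
    .check_mep(model, s$mep)
    if (length(s$glcm) != 64L) stop("GLCM feature vector must have length 64")
    .embed_fwd(model$params, model$config, s$mep, as.numeric(s$glcm))$e
  }, numeric(model$config$embedding_dim)))
  rownames(e) <- names(samples)
  e
}

.as_model <- function(x) {
  if (inherits(x, "siamese_fit")) x$model
  else if (inherits(x, "siamese_model")) x
  else stop("expected a siamese_model or siamese_fit")
}

#' Euclidean distance between two embeddings
#'
#' @param e1,e2 Numeric embedding vectors of equal length.
#' @return Non-negative distance.
#' @export
pairwise_distance <- function(e1, e2) {
  if (length(e1) != length(e2)) stop("embedding dimension mismatch")
  sqrt(sum((e1 - e2)^2))
}

#' Inverse-distance similarity
#'
#' Maps an embedding distance `d >= 0` to the similarity score
#' \eqn{d^{-1} = 1 / (1 + d)}: a strictly decreasing bijection from
#' \[0, Inf) onto (0, 1\], equal to 1 iff the embeddings coincide.
#'
#' @param d Non-negative distance (vectorized).
#' @return Similarity in (0, 1\].
#' @export
inverse_distance <- function(d) {
  if (any(d < 0)) stop("distance must be >= 0")
  1 / (1 + d)
}

#' Triplet loss
#'
#' \eqn{\max(0, d(a,p) - d(a,n) + margin)}: pulls the positive inside the
#' margin, pushes the negative out.
#'
#' @param ea,ep,en Anchor, positive, negative embeddings (equal length).
#' @param margin Positive margin.
#' @return Non-negative loss value.
#' @export
triplet_loss <- function(ea, ep, en, margin = 1) {
  if (length(ea) != length(ep) || length(ea) != length(en)) {
    stop("embedding dimension mismatch")
  }
  max(0, pairwise_distance(ea, ep) - pairwise_distance(ea, en) + margin)
}

#' Inverse-distance similarity matrix
#'
#' @param embeddings Matrix with one embedding per row (rownames = ids), or
#'   a named list of embedding vectors.
#' @return Square symmetric matrix of `1/(1+d)` values with unit diagonal.
#' @export
inverse_distance_matrix <- function(embeddings) {
  e <- if (is.list(embeddings)) do.call(rbind, embeddings) else embeddings
  if (nrow(e) < 2L) stop("need at least 2 embeddings")
  d <- as.matrix(stats::dist(e))
  m <- 1 / (1 + d)
  diag(m) <- 1
  dimnames(m) <- list(rownames(e), rownames(e))
  m
}

#' Preprocess an MEP image for the CNN branch
#'
#' Scales pixel values to \[0, 1\] and bilinearly resizes to the model's
#' square input resolution.
#'
#' @param img `H x W x 3` array in 0..255 (see [load_image()]).
#' @param input_size Target side length in pixels.
#' @return `input_size x input_size x 3` array in \[0, 1\].
#' @export
preprocess_mep <- function(img, input_size = 64L) {
  x <- img / 255
  .resize_bilinear(x, input_size, input_size)
}

# Bilinear resize of an H x W x C array (align-corners-free convention).
.resize_bilinear <- function(x, ho, wo) {
  d <- dim(x); hi <- d[1]; wi <- d[2]
  if (hi == ho && wi == wo) return(x)
  sy <- hi / ho; sx <- wi / wo
  fy <- pmin(pmax((seq_len(ho) - 0.5) * sy - 0.5, 0), hi - 1)
  fx <- pmin(pmax((seq_len(wo) - 0.5) * sx - 0.5, 0), wi - 1)
  y0 <- pmin(floor(fy), hi - 1); y1 <- pmin(y0 + 1, hi - 1)
  x0 <- pmin(floor(fx), wi - 1); x1 <- pmin(x0 + 1, wi - 1)
  wy <- fy - y0; wx <- fx - x0
  out <- array(0, c(ho, wo, d[3]))
  for (c in seq_len(d[3])) {
    pl <- x[, , c]
    a <- pl[cbind(rep(y0 + 1, wo), rep(x0 + 1, each = ho))]
    b <- pl[cbind(rep(y1 + 1, wo), rep(x0 + 1, each = ho))]
    cc <- pl[cbind(rep(y0 + 1, wo), rep(x1 + 1, each = ho))]
    dd <- pl[cbind(rep(y1 + 1, wo), rep(x1 + 1, each = ho))]
    wyv <- rep(wy, wo); wxv <- rep(wx, each = ho)
    out[, , c] <- matrix((1 - wyv) * (1 - wxv) * a + wyv * (1 - wxv) * b +
                           (1 - wyv) * wxv * cc + wyv * wxv * dd, ho, wo)
  }
  out
}

#' Load multimodal samples from a manifest
#'
#' Reads every compound's MEP image (preprocessed for the CNN branch) and
#' RDG image (converted to the 64-d GLCM texture vector).
#'
#' @param manifest Data frame from [read_manifest()] (or with the same
#'   columns).
#' @param input_size CNN input resolution (default 64).
#' @param glcm_args Optional list of extra arguments for [glcm()].
#' @return Named list of samples, each `list(id, mep, glcm)`.
#' @export
load_samples <- function(manifest, input_size = 64L, glcm_args = list()) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    mep <- preprocess_mep(load_image(row$mep_path), input_size)
    q <- quantize(load_image(row$rdg_path), 8L)
    g <- do.call(glcm, c(list(q), glcm_args))
    list(id = row$id, mep = mep, glcm = glcm_feature(g))
  })
  names(out) <- manifest$id
  out
}
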