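# The two-branch network: branch contracts, fusion, distances, triplet loss.

tiny_model <- function(seed = 5L) {
  siamese_model(embedding_dim = 8L, conv_filters = c(4L, 8L),
                mlp_hidden = c(16L, 8L), projector_hidden = 12L,
                input_size = 16L, seed = seed)
}

rand_sample <- function(seed = 1L, size = 16L) {
  set.seed(seed)
  g <- stats::runif(64); g <- g / sum(g)
  list(mep = array(stats::runif(size * size * 3), c(size, size, 3)),
       glcm = g)
}

test_that("model constructor validates its configuration", {
  expect_error(siamese_model(margin = 0), "margin")
  expect_error(siamese_model(embedding_dim = 0), "positive")
  expect_error(siamese_model(input_size = 50), "divisible")
  expect_error(siamese_model(kernel_size = 4), "odd")
  m <- tiny_model()
  expect_s3_class(m, "siamese_model")
  expect_output(print(m), "Siamese")
})

test_that("CNN branch is deterministic with fixed weights and checks shape", {
  m <- tiny_model()
  s <- rand_sample()
  v1 <- cnn_branch(m, s$mep)
  v2 <- cnn_branch(m, s$mep)
  expect_identical(v1, v2)
  expect_length(v1, 8L)          # last conv filter count
  expect_true(all(is.finite(v1)))
  expect_true(all(is.finite(cnn_branch(m, array(0, c(16, 16, 3))))))
  expect_error(cnn_branch(m, array(0, c(8, 8, 3))), "16")
})

test_that("MLP branch maps a 64-vector to the configured feature size", {
  m <- tiny_model()
  s <- rand_sample()
  t1 <- mlp_branch(m, s$glcm)
  expect_identical(t1, mlp_branch(m, s$glcm))
  expect_length(t1, 8L)          # last MLP layer size
  expect_error(mlp_branch(m, numeric(63)), "64")
})

test_that("fusion projects to the embedding dimension and uses both modalities", {
  m <- tiny_model()
  s <- rand_sample()
  v <- cnn_branch(m, s$mep)
  tx <- mlp_branch(m, s$glcm)
  e <- fuse_project(m, v, tx)
  expect_length(e, 8L)
  e0 <- fuse_project(m, v, tx * 0)
  expect_gt(max(abs(e - e0)), 0)
  mn <- siamese_model(embedding_dim = 8L, conv_filters = c(4L, 8L),
                      mlp_hidden = c(16L, 8L), projector_hidden = 12L,
                      input_size = 16L, seed = 5L,
                      normalize_embeddings = TRUE)
  en <- fuse_project(mn, v, tx)
  expect_equal(sqrt(sum(en^2)), 1, tolerance = 1e-6)
  expect_error(fuse_project(m, v, numeric(3)), "length")
})

test_that("embedding matches the branch-then-fuse decomposition", {
  m <- tiny_model()
  s <- rand_sample(2)
  e <- embed_samples(m, s)[1, ]
  expect_equal(e, fuse_project(m, cnn_branch(m, s$mep), mlp_branch(m, s$glcm)))
})

test_that("pairwise distance is Euclidean and symmetric", {
  expect_equal(pairwise_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pairwise_distance(c(1, 2), c(1, 2)), 0)
  x <- stats::rnorm(8); y <- stats::rnorm(8)
  expect_equal(pairwise_distance(x, y), pairwise_distance(y, x))
  expect_error(pairwise_distance(1:3, 1:4), "mismatch")
})

test_that("inverse distance is 1/(1+d), strictly decreasing onto (0,1]", {
  expect_equal(inverse_distance(0), 1)
  expect_equal(inverse_distance(1), 0.5)
  expect_equal(inverse_distance(3), 0.25)
  d <- sort(stats::runif(20, 0, 50))
  v <- inverse_distance(d)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= 1))
  expect_error(inverse_distance(-0.1), ">= 0")
})

test_that("triplet loss reproduces hand arithmetic", {
  # 1-d embeddings: distances are absolute differences
  expect_equal(triplet_loss(e1(0), e1(0.2), e1(1.0), margin = 0.5), 0)
  expect_equal(triplet_loss(e1(0), e1(1.0), e1(0.2), margin = 0.5), 1.3)
  expect_equal(triplet_loss(e1(0.7), e1(0.7), e1(1.0), margin = 0.5),
               max(0, 0.5 - 0.3))
  expect_error(triplet_loss(1:2, 1:3, 1:2), "mismatch")
  set.seed(41)
  for (i in 1:10) {
    ea <- stats::rnorm(4); ep <- stats::rnorm(4); en <- stats::rnorm(4)
    l <- triplet_loss(ea, ep, en, margin = 0.8)
    expect_gte(l, 0)
    expect_equal(l == 0,
                 pairwise_distance(ea, en) >=
                   pairwise_distance(ea, ep) + 0.8)
  }
})

test_that("inverse-distance matrix matches entry-wise recomputation", {
  set.seed(42)
  E <- matrix(stats::rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("c", 1:5), NULL))
  m <- inverse_distance_matrix(E)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 5))
  expect_true(all(m > 0 & m <= 1))
  for (i in 1:5) for (j in 1:5) {
    if (i != j) {
      expect_equal(m[i, j],
                   inverse_distance(pairwise_distance(E[i, ], E[j, ])))
    }
  }
  same <- inverse_distance_matrix(rbind(a = c(1, 2), b = c(1, 2),
                                        c = c(1, 2)))
  expect_equal(unname(same), matrix(1, 3, 3))
})

test_that("analytic parameter gradients agree with finite differences", {
  ns <- asNamespace("mepsim")
  m <- tiny_model(seed = 9L)
  s <- rand_sample(3)
  ref <- stats::rnorm(8)
  fobj <- function(params) {
    e <- ns$.embed_fwd(params, m$config, s$mep, s$glcm)$e
    -sum((e - ref)^2)
  }
  f <- ns$.embed_fwd(m$params, m$config, s$mep, s$glcm)
  bw <- ns$.embed_bwd(m$params, m$config, f$cache, -2 * (f$e - ref))
  eps <- 1e-6
  set.seed(43)
  for (nm in c("conv1_W", "mlp1_W", "proj2_W", "conv2_b")) {
    idx <- sample(length(m$params[[nm]]), 3)
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps; up <- fobj(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- fobj(pp)
      expect_equal(bw$grads[[nm]][i], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("MEP preprocessing scales and resizes", {
  img <- array(as.integer(round(255 * stats::runif(32 * 48 * 3))),
               c(32, 48, 3))
  out <- preprocess_mep(img, 16L)
  expect_identical(dim(out), c(16L, 16L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  flat <- preprocess_mep(array(128L, c(20, 20, 3)), 16L)
  expect_equal(as.vector(flat), rep(128 / 255, 16 * 16 * 3))
})
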