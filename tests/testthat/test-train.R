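# Splitting, early stopping, and the training loop.

test_that("triplet split is disjoint, exhaustive, and seed-deterministic", {
  tri <- data.frame(anchor = letters[1:10], positive = LETTERS[1:10],
                    negative = rev(letters[1:10]))
  sp <- split_triplets(tri, 0.2, seed = 7)
  expect_identical(nrow(sp$train), 8L)
  expect_identical(nrow(sp$val), 2L)
  both <- rbind(sp$train, sp$val)
  expect_setequal(paste(both$anchor, both$positive), paste(tri$anchor, tri$positive))
  expect_identical(split_triplets(tri, 0.2, seed = 7), sp)
  expect_false(identical(split_triplets(tri, 0.2, seed = 8)$val, sp$val))
  expect_error(split_triplets(tri, 1.2), "val_fraction")
  expect_error(split_triplets(tri[1, ], 0.2), "at least 2")
})

test_that("early stopping fires only after a patience-long plateau", {
  expect_false(early_stop(c(1.0, 0.9, 0.8), patience = 2))
  expect_true(early_stop(c(1.0, 1.1, 1.2, 1.3), patience = 3))
  expect_false(early_stop(c(1.0), patience = 3))
  # improvement below min_delta does not reset the counter
  expect_true(early_stop(c(1.0, 1.0 - 1e-6, 1.0 - 2e-6), patience = 2))
  # monotone decrease from epoch 2 upward: stop exactly patience epochs later
  seqs <- c(0.5, 0.4, 0.41, 0.42, 0.43, 0.44)
  stops <- vapply(seq_along(seqs), function(k) {
    early_stop(seqs[1:k], patience = 3)
  }, logical(1))
  expect_identical(which(stops)[1], 5L)   # best at 2, stop at 2 + 3
  expect_error(early_stop(numeric(0), 2), "at least one")
})

test_that("training reduces the loss on the 2-family benchmark and restores the best checkpoint", {
  fit <- small_fit()
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  expect_identical(nrow(h), fit$stopped_epoch)
  expect_equal(min(h$val_loss), h$val_loss[fit$best_epoch])
  # restored checkpoint reproduces the best validation loss
  vE <- embed_samples(fit$model, bench_samples(16L))
  val <- fit$split$val
  ns <- asNamespace("mepsim")
  vloss <- ns$.triplet_pass(vE, val, fit$model$config$margin)$loss
  expect_equal(vloss, min(h$val_loss), tolerance = 1e-9)
})

test_that("training is reproducible under a fixed seed", {
  model <- siamese_model(embedding_dim = 8L, conv_filters = c(4L, 8L),
                         mlp_hidden = c(8L, 8L), projector_hidden = 8L,
                         input_size = 16L, seed = 11L)
  tri <- bench_triplets()[seq(1, 896, by = 12), ]
  f1 <- fit_siamese(model, bench_samples(16L), tri, max_epochs = 3L,
                    patience = 3L, seed = 2L)
  f2 <- fit_siamese(model, bench_samples(16L), tri, max_epochs = 3L,
                    patience = 3L, seed = 2L)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("missing samples are reported with the affected triplet", {
  tri <- data.frame(anchor = "ghost", positive = "fam1_01",
                    negative = "fam2_01")
  tri <- rbind(tri, tri)
  expect_error(
    fit_siamese(siamese_model(input_size = 16L, conv_filters = c(4L, 8L),
                              mlp_hidden = c(8L, 8L), projector_hidden = 8L,
                              embedding_dim = 8L),
                bench_samples(16L), tri),
    "ghost")
})

test_that("patience must not exceed the epoch cap and the cap is honored", {
  model <- siamese_model(embedding_dim = 8L, conv_filters = c(4L, 8L),
                         mlp_hidden = c(8L, 8L), projector_hidden = 8L,
                         input_size = 16L, seed = 1L)
  expect_error(fit_siamese(model, bench_samples(16L), bench_triplets(),
                           max_epochs = 2L, patience = 5L), "patience")
  tri <- bench_triplets()[seq(1, 896, by = 30), ]
  f <- fit_siamese(model, bench_samples(16L), tri, max_epochs = 2L,
                   patience = 2L, seed = 1L)
  expect_lte(f$stopped_epoch, 2L)
})

test_that("checkpoints and histories round-trip through disk", {
  dir <- withr::local_tempdir()
  fit <- small_fit()
  p <- save_checkpoint(fit, file.path(dir, "ck.rds"))
  back <- load_checkpoint(p)
  expect_identical(back$model$params, fit$model$params)
  expect_identical(back$history, fit$history)
  write_history_csv(fit, file.path(dir, "h.csv"))
  h <- utils::read.csv(file.path(dir, "h.csv"))
  expect_equal(h$val_loss, fit$history$val_loss, tolerance = 1e-12)
  expect_error(load_checkpoint(file.path(dir, "nope.rds")), "not found")
})
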