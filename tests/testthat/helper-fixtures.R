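# Shared fixtures (memoized per test session) and independent brute-force
# oracles used by the unit and acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  got <- .fixture_env[[key]]
  if (!is.null(got)) return(got)
  val <- force(expr)
  assign(key, val, envir = .fixture_env)
  val
}

bench_manifest <- function() memo("manifest", {
  dir <- file.path(tempdir(), "mepsim-bench")
  make_benchmark(dir, n_families = 2L, per_family = 8L, seed = 1L)
})

bench_sim <- function() memo("sim", similarity_matrix(bench_manifest()))

bench_triplets <- function() memo("triplets", {
  mine_triplets(bench_sim(), triplet_config(0.70, 0.40, "all"))
})

bench_samples <- function(input_size = 64L) {
  memo(paste0("samples", input_size), {
    load_samples(bench_manifest(), input_size = input_size)
  })
}

# Small, fast fit for interpretability/training unit tests.
small_fit <- function() memo("small_fit", {
  model <- siamese_model(embedding_dim = 16L, conv_filters = c(8L, 16L),
                         mlp_hidden = c(32L, 16L), projector_hidden = 24L,
                         input_size = 16L, seed = 3L)
  fit_siamese(model, bench_samples(16L), bench_triplets(), max_epochs = 6L,
              patience = 3L, seed = 3L)
})

# Default-configuration 20-epoch benchmark fit (the end-to-end separation
# surface); shared between acceptance checks.
full_fit <- function() memo("full_fit", {
  fit_siamese(siamese_model(seed = 1L), bench_samples(64L),
              bench_triplets(), max_epochs = 20L, patience = 5L, seed = 1L)
})

# --- independent oracles ----------------------------------------------------

# Exhaustive pair-enumeration GLCM: walks every pixel and offset explicitly.
glcm_bruteforce <- function(q, offsets, symmetric = TRUE, normalize = TRUE) {
  levels <- attr(q, "levels")
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    dy <- off[[1]]; dx <- off[[2]]
    for (i in seq_len(nrow(q))) {
      for (j in seq_len(ncol(q))) {
        i2 <- i + dy; j2 <- j + dx
        if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
          a <- q[i, j] + 1L; b <- q[i2, j2] + 1L
          counts[a, b] <- counts[a, b] + 1
          if (symmetric) counts[b, a] <- counts[b, a] + 1
        }
      }
    }
  }
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

rand_grid <- function(h, w, levels = 8L) {
  q <- matrix(sample.int(levels, h * w, replace = TRUE) - 1L, h, w)
  attr(q, "levels") <- levels
  q
}

# Exhaustive three-loop triplet enumeration applying the threshold rule.
mine_bruteforce <- function(sim, pos, neg, anchors = rownames(sim)) {
  out <- list()
  for (a in sort(anchors)) {
    for (p in sort(rownames(sim))) {
      for (n in sort(rownames(sim))) {
        if (a != p && a != n && p != n &&
            sim[a, p] >= pos && sim[a, n] <= neg) {
          out[[length(out) + 1L]] <- data.frame(
            anchor = a, positive = p, negative = n,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(anchor = character(0), positive = character(0),
                      negative = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$anchor, df$positive, df$negative), ]
  rownames(df) <- NULL
  df
}

random_sim_matrix <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  m
}

# Embeds a scalar as a 1-d "embedding" so distances are |a-b|.
e1 <- function(x) as.numeric(x)
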