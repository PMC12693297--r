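# Synthetic fixtures: MEP-like and RDG-like image families plus matched toy
# SMILES pools, so the full pipeline (fingerprints -> triplets -> training
# -> interpretation) runs without quantum-chemistry data.
#
# MEP surrogates are smooth signed Gaussian "potential" fields rendered
# through a diverging colormap; RDG surrogates are sparse white-background
# scatter diagrams with family-specific vertical spikes, mimicking the
# density/gradient spike plots of non-covalent-interaction analysis.
# Neither is physically meaningful; they reproduce the visual statistics
# the two branches consume (smooth colored blobs; sparse textured spikes).

# Curated homologous SMILES series. Within a series, binary Morgan
# fingerprints are nearly saturated (pairwise Tanimoto >= 0.87); across
# series they share almost nothing (<= 0.37). Validated again at
# generation time against the 0.70/0.40 triplet thresholds.
.smiles_pools <- list(
  alkane = sapply(6:13, function(n) paste(rep("C", n), collapse = "")),
  glycol = sapply(1:8, function(n) {
    paste0("OCC", paste(rep("OCC", n), collapse = ""), "O")
  }),
  aniline = sapply(8:15, function(n) {
    paste0("Nc1ccc(cc1)", paste(rep("C", n), collapse = ""))
  })
)

.derive_seed <- function(seed, family_id, member_idx, salt = 0L) {
  h <- sum(utf8ToInt(family_id) * seq_along(utf8ToInt(family_id)))
  as.integer((as.numeric(seed) * 7919 + h * 131 + member_idx * 17 + salt) %%
               2147483647)
}

#' Specification of one synthetic image family
#'
#' @param family_id Short label.
#' @param n_members Number of members to generate.
#' @param centers `k x 2` matrix of Gaussian blob centers in \[0, 1\]^2.
#' @param widths Length-`k` blob widths (fraction of image side).
#' @param signs Length-`k` blob polarities (+1 / -1), coloring the MEP
#'   surrogate red or blue.
#' @param jitter Per-member perturbation SD of centers (image fraction);
#'   keep well below the between-family layout separation.
#' @param rdg_peaks Horizontal positions in \[0, 1\] of the RDG spike
#'   clusters.
#' @param smiles_pool Character vector of SMILES sharing a scaffold.
#' @return A list of class `"family_spec"`.
#' @export
family_spec <- function(family_id, n_members, centers, widths, signs,
                        jitter = 0.02, rdg_peaks, smiles_pool) {
  if (!length(smiles_pool)) stop("smiles_pool must be non-empty")
  if (n_members > length(smiles_pool)) {
    stop("n_members exceeds smiles_pool size")
  }
  structure(list(family_id = family_id, n_members = n_members,
                 centers = centers, widths = widths, signs = signs,
                 jitter = jitter, rdg_peaks = rdg_peaks,
                 smiles_pool = smiles_pool),
            class = "family_spec")
}

.default_specs <- function(n_families) {
  layouts <- list(
    list(centers = rbind(c(0.30, 0.35), c(0.70, 0.60), c(0.45, 0.75)),
         widths = c(0.16, 0.12, 0.09), signs = c(1, -1, 1),
         rdg_peaks = c(0.25, 0.55)),
    list(centers = rbind(c(0.65, 0.30), c(0.30, 0.70)),
         widths = c(0.22, 0.10), signs = c(-1, 1),
         rdg_peaks = c(0.40, 0.70, 0.85)),
    list(centers = rbind(c(0.50, 0.50), c(0.20, 0.25), c(0.80, 0.30),
                         c(0.25, 0.80)),
         widths = c(0.10, 0.08, 0.12, 0.07), signs = c(1, 1, -1, -1),
         rdg_peaks = c(0.15, 0.60))
  )
  if (n_families > length(.smiles_pools)) {
    stop("at most ", length(.smiles_pools),
         " families available (one curated SMILES pool each)")
  }
  lapply(seq_len(n_families), function(f) {
    ly <- layouts[[(f - 1L) %% length(layouts) + 1L]]
    family_spec(paste0("fam", f), n_members = 8L, centers = ly$centers,
                widths = ly$widths, signs = ly$signs, jitter = 0.02,
                rdg_peaks = ly$rdg_peaks,
                smiles_pool = .smiles_pools[[f]])
  })
}

#' Generate a synthetic MEP-like image
#'
#' A smooth field of signed Gaussian blobs (family layout, per-member
#' jittered centers/widths) rendered through a red-white-blue diverging
#' colormap, emulating a rendered electrostatic-potential surface.
#' Deterministic per `(spec, member_idx, seed)`; two members of one family
#' are correlated (pixel correlation typically > 0.5 at the default
#' jitter).
#'
#' @param spec A [family_spec()].
#' @param member_idx Member index (1-based).
#' @param seed Integer master seed.
#' @param size Square image side in pixels (>= 32; default 128).
#' @return Integer array `size x size x 3` in 0..255.
#' @export
make_mep_image <- function(spec, member_idx, seed = 1L, size = 128L) {
  if (size < 32L) stop("'size' must be >= 32")
  .with_seed(.derive_seed(seed, spec$family_id, member_idx, 1L), {
    k <- nrow(spec$centers)
    ctr <- spec$centers + matrix(stats::rnorm(2 * k, sd = spec$jitter), k, 2)
    wid <- spec$widths * exp(stats::rnorm(k, sd = 0.08))
    ax <- (seq_len(size) - 0.5) / size
    field <- matrix(0, size, size)
    for (j in seq_len(k)) {
      g <- outer((ax - ctr[j, 2])^2, (ax - ctr[j, 1])^2, "+")
      field <- field + spec$signs[j] * exp(-g / (2 * wid[j]^2))
    }
    vn <- field / max(abs(field), 1e-12)
    img <- array(0, c(size, size, 3))
    img[, , 1] <- 1 - pmax(-vn, 0)
    img[, , 2] <- 1 - abs(vn) * 0.85
    img[, , 3] <- 1 - pmax(vn, 0)
    array(as.integer(round(img * 255)), dim(img))
  })
}

#' Generate a synthetic RDG-like scatter diagram
#'
#' A white-background scatter plot with dense vertical point clusters
#' ("spikes") at family-specific horizontal positions, emulating a reduced
#' density gradient vs. electron density diagram. Deterministic per
#' arguments; well over half the pixels remain background.
#'
#' @inheritParams make_mep_image
#' @return Integer array `size x size x 3` in 0..255.
#' @export
make_rdg_image <- function(spec, member_idx, seed = 1L, size = 128L) {
  if (size < 32L) stop("'size' must be >= 32")
  .with_seed(.derive_seed(seed, spec$family_id, member_idx, 2L), {
    img <- array(1, c(size, size, 3))
    npts <- 160L
    for (p in spec$rdg_peaks) {
      px <- p + stats::rnorm(1, sd = spec$jitter)    # member-level shift
      x <- px + stats::rnorm(npts, sd = 0.012)
      y <- 1 - stats::rbeta(npts, 1.3, 4)            # dense near the bottom
      ix <- pmin(pmax(round(x * (size - 1)) + 1L, 1L), size)
      iy <- pmin(pmax(round(y * (size - 1)) + 1L, 1L), size)
      col <- c(pmin(2 * px, 1), 0.2, pmin(2 * (1 - px), 1))
      for (t in seq_len(npts)) {
        img[iy[t], ix[t], ] <- col
      }
    }
    array(as.integer(round(img * 255)), dim(img))
  })
}

#' Generate a complete synthetic benchmark on disk
#'
#' Writes MEP and RDG PNGs for `n_families x per_family` compounds plus a
#' manifest CSV (`id,smiles,mep_path,rdg_path`). SMILES come from curated
#' homologous pools so intra-family Tanimoto is >= 0.70 and inter-family
#' <= 0.40, guaranteeing non-empty triplet mining at the default
#' thresholds; the pools are re-validated at generation time and a
#' violation aborts with the offending pairs. A GLCM-space self-test
#' additionally checks that within-family texture distances are smaller on
#' average than between-family distances.
#'
#' @param dir Output directory (created if missing).
#' @param n_families Number of families (>= 2; at most the number of
#'   curated pools).
#' @param per_family Members per family (<= 8).
#' @param seed Integer master seed.
#' @param size Image side in pixels (default 128).
#' @param validate Run the threshold and texture self-tests (default
#'   `TRUE`).
#' @return The manifest data frame (with absolute image paths), invisibly
#'   written to `file.path(dir, "manifest.csv")`.
#' @export
make_benchmark <- function(dir, n_families = 2L, per_family = 8L, seed = 1L,
                           size = 128L, validate = TRUE) {
  if (n_families < 2L) stop("'n_families' must be >= 2")
  specs <- .default_specs(n_families)
  if (per_family > min(lengths(lapply(specs, `[[`, "smiles_pool")))) {
    stop("'per_family' exceeds the curated SMILES pool size")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (f in seq_len(n_families)) {
    sp <- specs[[f]]
    for (m in seq_len(per_family)) {
      id <- sprintf("%s_%02d", sp$family_id, m)
      mep <- make_mep_image(sp, m, seed, size)
      rdg <- make_rdg_image(sp, m, seed, size)
      mp <- file.path(dir, paste0(id, "_mep.png"))
      rp <- file.path(dir, paste0(id, "_rdg.png"))
      png::writePNG(mep / 255, mp)
      png::writePNG(rdg / 255, rp)
      rows[[id]] <- data.frame(id = id, smiles = sp$smiles_pool[[m]],
                               mep_path = mp, rdg_path = rp,
                               family = sp$family_id,
                               stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (validate) .validate_benchmark(manifest)
  portable <- manifest[c("id", "smiles", "mep_path", "rdg_path")]
  portable$mep_path <- basename(portable$mep_path)   # resolved by
  portable$rdg_path <- basename(portable$rdg_path)   # read_manifest()
  utils::write.csv(portable, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

# Threshold contract on the SMILES pools + GLCM-space family separation.
.validate_benchmark <- function(manifest, pos = 0.70, neg = 0.40) {
  sim <- similarity_matrix(manifest)
  fam <- manifest$family
  same <- outer(fam, fam, "==")
  off <- !diag(nrow(sim))
  bad_intra <- which(same & off & sim < pos, arr.ind = TRUE)
  bad_inter <- which(!same & sim > neg, arr.ind = TRUE)
  fmt <- function(ix) paste(unique(apply(ix, 1, function(r) {
    paste(sort(manifest$id[r]), collapse = "~")
  })), collapse = ", ")
  if (nrow(bad_intra)) {
    stop("intra-family Tanimoto below ", pos, " for: ", fmt(bad_intra))
  }
  if (nrow(bad_inter)) {
    stop("inter-family Tanimoto above ", neg, " for: ", fmt(bad_inter))
  }
  feats <- t(vapply(manifest$rdg_path, rdg_texture_feature, numeric(64)))
  fd <- as.matrix(stats::dist(feats))
  within <- mean(fd[same & off])
  between <- mean(fd[!same])
  if (!(within < between)) {
    stop("generator self-test failed: GLCM families not separated (",
         "within ", signif(within, 3), " >= between ", signif(between, 3), ")")
  }
  invisible(TRUE)
}
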