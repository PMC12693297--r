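# Chemistry layer: SMILES parsing, Morgan fingerprints, Tanimoto similarity.
#
# Fingerprinting is delegated to RDKit's Morgan generator through a batched
# subprocess bridge (inst/python/morgan_fp.py), so scores agree bit-for-bit
# with the standard cheminformatics toolchain. Results are cached per session.

.fp_cache <- new.env(parent = emptyenv())

.python_bin <- function() {
  bin <- getOption("mepsim.python", Sys.which("python"))
  if (!nzchar(bin)) {
    stop("No 'python' executable found; RDKit is required for fingerprinting.",
         call. = FALSE)
  }
  bin
}

# Batched bridge: one subprocess call for a vector of SMILES.
# Returns a list (one element per input) of
#   list(ok = TRUE, canonical = chr, on = 1-based integer on-bit indices)
# or list(ok = FALSE) for unparsable SMILES.
.rdkit_batch <- function(smiles, radius = 2L, nbits = 2048L, chiral = FALSE) {
  key <- function(s) paste(s, radius, nbits, chiral, sep = "\r")
  out <- vector("list", length(smiles))
  todo <- which(!vapply(smiles, function(s) {
    !is.null(.fp_cache[[key(s)]])
  }, logical(1)))
  if (length(todo)) {
    script <- system.file("python", "morgan_fp.py", package = "mepsim")
    if (!nzchar(script)) stop("bundled fingerprint helper not found")
    res <- suppressWarnings(system2(
      .python_bin(), c(shQuote(script), radius, nbits, if (chiral) "1" else "0"),
      input = smiles[todo], stdout = TRUE, stderr = FALSE
    ))
    if (length(res) != length(todo)) {
      stop("fingerprint helper failed (is RDKit importable from 'python'?)")
    }
    for (i in seq_along(todo)) {
      fields <- strsplit(res[[i]], "\t", fixed = TRUE)[[1]]
      rec <- if (fields[[1]] == "OK") {
        on <- if (length(fields) >= 3 && nzchar(fields[[3]])) {
          as.integer(strsplit(fields[[3]], ",", fixed = TRUE)[[1]]) + 1L
        } else integer(0)
        list(ok = TRUE, canonical = fields[[2]], on = on)
      } else {
        list(ok = FALSE)
      }
      assign(key(smiles[[todo[[i]]]]), rec, envir = .fp_cache)
    }
  }
  lapply(smiles, function(s) .fp_cache[[key(s)]])
}

#' Parse a SMILES string
#'
#' Validates and canonicalizes a SMILES string. Two SMILES spellings of the
#' same molecule (e.g. `"CCO"` and `"OCC"`) yield the same canonical form, so
#' downstream fingerprints do not depend on the input dialect.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `"molecule"`: a list with elements `smiles`
#'   (the input) and `canonical` (the canonical SMILES).
#' @examples
#' \dontrun{
#' parse_smiles("OCC")$canonical  # "CCO"
#' }
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("'smiles' must be a single non-empty string")
  }
  rec <- .rdkit_batch(smiles)[[1]]
  if (!rec$ok) stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  structure(list(smiles = smiles, canonical = rec$canonical),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$canonical, "\n", sep = "")
  invisible(x)
}

#' Morgan (circular) fingerprint
#'
#' Computes a fixed-length binary Morgan fingerprint. Defaults (2048 bits,
#' radius 2, the ECFP4 convention) match the structural-similarity baseline
#' used throughout this package.
#'
#' @param mol A `"molecule"` from [parse_smiles()], or a SMILES string.
#' @param radius Non-negative circular radius (default 2).
#' @param nbits Positive fingerprint length in bits (default 2048).
#' @param chiral Include chirality in atom environments? Default `FALSE`.
#' @return An object of class `"fingerprint"`: list with `bits` (integer 0/1
#'   vector of length `nbits`), `on` (1-based indices of set bits), `nbits`,
#'   `radius`.
#' @export
morgan_fingerprint <- function(mol, radius = 2L, nbits = 2048L,
                               chiral = FALSE) {
  if (radius < 0) stop("'radius' must be >= 0")
  if (nbits <= 0) stop("'nbits' must be > 0")
  smi <- if (inherits(mol, "molecule")) mol$smiles else mol
  if (!is.character(smi) || length(smi) != 1L) {
    stop("'mol' must be a molecule or a single SMILES string")
  }
  rec <- .rdkit_batch(smi, as.integer(radius), as.integer(nbits), chiral)[[1]]
  if (!rec$ok) stop("unparsable SMILES: '", smi, "'", call. = FALSE)
  bits <- integer(nbits)
  bits[rec$on] <- 1L
  structure(list(bits = bits, on = rec$on, nbits = as.integer(nbits),
                 radius = as.integer(radius)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> ", x$nbits, " bits, radius ", x$radius, ", ",
      length(x$on), " set\n", sep = "")
  invisible(x)
}

.fp_bits <- function(x) {
  if (inherits(x, "fingerprint")) return(x$bits)
  if (is.numeric(x) || is.logical(x)) return(as.integer(x != 0))
  stop("expected a fingerprint or a binary vector")
}

#' Tanimoto similarity between two binary fingerprints
#'
#' \eqn{S_T(A, B) = |A \cap B| / |A \cup B|} over the set bits of two binary
#' fingerprints of equal length. When both fingerprints are all-zero the
#' ratio is 0/0; this is defined as 0 (no shared substructure evidence) with
#' a warning.
#'
#' @param a,b Fingerprints (from [morgan_fingerprint()]) or binary vectors of
#'   equal length.
#' @return A similarity score in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  av <- .fp_bits(a)
  bv <- .fp_bits(b)
  if (length(av) != length(bv)) {
    stop("fingerprint length mismatch: ", length(av), " vs ", length(bv))
  }
  inter <- sum(av & bv)
  union <- sum(av | bv)
  if (union == 0L) {
    warning("both fingerprints are empty; Tanimoto defined as 0")
    return(0)
  }
  inter / union
}

#' Pairwise Tanimoto similarity matrix
#'
#' Fingerprints every compound (one batched call) and fills the symmetric
#' matrix of pairwise Tanimoto scores with unit diagonal.
#'
#' @param compounds Either a data frame with columns `id` and `smiles` (a
#'   manifest, see [read_manifest()]) or a named character vector of SMILES.
#' @param radius,nbits,chiral Fingerprint parameters, see
#'   [morgan_fingerprint()].
#' @return A square numeric matrix with compound ids as dimnames, entries in
#'   \[0, 1\], symmetric with unit diagonal.
#' @export
similarity_matrix <- function(compounds, radius = 2L, nbits = 2048L,
                              chiral = FALSE) {
  if (is.data.frame(compounds)) {
    ids <- as.character(compounds$id)
    smiles <- as.character(compounds$smiles)
  } else {
    smiles <- as.character(compounds)
    ids <- names(compounds)
    if (is.null(ids)) ids <- paste0("cpd", seq_along(smiles))
  }
  if (length(smiles) < 2L) stop("need at least 2 compounds")
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  recs <- .rdkit_batch(smiles, as.integer(radius), as.integer(nbits), chiral)
  bad <- !vapply(recs, `[[`, logical(1), "ok")
  if (any(bad)) {
    stop("invalid SMILES for compound(s): ", paste(ids[bad], collapse = ", "))
  }
  onsets <- lapply(recs, `[[`, "on")
  n <- length(ids)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      inter <- length(intersect(onsets[[i]], onsets[[j]]))
      union <- length(onsets[[i]]) + length(onsets[[j]]) - inter
      m[i, j] <- m[j, i] <- if (union == 0L) 0 else inter / union
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Read a compound manifest
#'
#' The manifest is a CSV with header `id,smiles,mep_path,rdg_path` mapping
#' each compound to its identifier, SMILES string, MEP image and RDG image.
#' Relative image paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame with the four manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "mep_path", "rdg_path")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("duplicate compound ids in manifest")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$mep_path <- fix(df$mep_path)
  df$rdg_path <- fix(df$rdg_path)
  df[need]
}

#' Export a similarity matrix as CSV
#'
#' Writes the matrix with an id header row and column. Values are written at
#' full precision; use `digits` to round (similarity scores are conventionally
#' printed to 3 decimals).
#'
#' @param m Square similarity matrix with dimnames.
#' @param path Output CSV path.
#' @param digits Optional rounding for the written values.
#' @export
write_similarity_csv <- function(m, path, digits = NULL) {
  x <- if (is.null(digits)) m else round(m, digits)
  utils::write.csv(as.data.frame(x), path, row.names = TRUE)
  invisible(path)
}

#' Render a similarity matrix heatmap to PNG
#'
#' @param m Square similarity matrix with dimnames.
#' @param file Output PNG path.
#' @param main Plot title.
#' @param zlim Color range (default the full \[0, 1\] similarity scale).
#' @export
plot_similarity_heatmap <- function(m, file, main = "similarity",
                                    zlim = c(0, 1)) {
  n <- nrow(m)
  grDevices::png(file, width = 640, height = 600)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(6, 6, 3, 2))
  on.exit(graphics::par(op), add = TRUE)
  pal <- grDevices::hcl.colors(64, "viridis")
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  col = pal, zlim = zlim, axes = FALSE, xlab = "", ylab = "",
                  main = main)
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2)
  invisible(file)
}
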