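# Static triplet mining from a Tanimoto similarity matrix.
#
# Positives/negatives are defined per anchor by similarity thresholds; the
# standard regime is ST >= 0.70 (positive) / ST <= 0.40 (negative). A "hard"
# regime with a nearly closed gap (e.g. 0.13/0.12) yields triplets whose
# positives are barely more anchor-similar than their negatives.

#' Triplet mining configuration
#'
#' @param pos_thresh Lower Tanimoto bound for positives (default 0.70).
#' @param neg_thresh Upper Tanimoto bound for negatives (default 0.40).
#'   Must satisfy `0 <= neg_thresh < pos_thresh <= 1`; the gap may be
#'   arbitrarily small (hard-triplet regime, e.g. 0.13/0.12).
#' @param anchors Character vector of anchor compound ids, or `"all"`.
#' @return A list of class `"triplet_config"`.
#' @export
triplet_config <- function(pos_thresh = 0.70, neg_thresh = 0.40,
                           anchors = "all") {
  if (!(neg_thresh >= 0 && neg_thresh < pos_thresh && pos_thresh <= 1)) {
    stop("need 0 <= neg_thresh < pos_thresh <= 1")
  }
  structure(list(pos_thresh = pos_thresh, neg_thresh = neg_thresh,
                 anchors = anchors),
            class = "triplet_config")
}

#' Classify compounds as positives/negatives for an anchor
#'
#' Positives are compounds with similarity to the anchor at or above
#' `pos_thresh`; negatives at or below `neg_thresh`. Compounds strictly
#' between the thresholds are discarded.
#'
#' @param anchor_id Anchor compound id (must be in the matrix).
#' @param sim Square similarity matrix with id dimnames
#'   (see [similarity_matrix()]).
#' @param config A [triplet_config()].
#' @return List with character vectors `positives` and `negatives`, each
#'   sorted lexicographically.
#' @export
classify_compounds <- function(anchor_id, sim, config = triplet_config()) {
  ids <- rownames(sim)
  if (!(anchor_id %in% ids)) stop("unknown anchor id: ", anchor_id)
  s <- sim[anchor_id, ]
  others <- setdiff(ids, anchor_id)
  list(
    positives = sort(others[s[others] >= config$pos_thresh]),
    negatives = sort(others[s[others] <= config$neg_thresh])
  )
}

#' Mine (anchor, positive, negative) triplets
#'
#' For each anchor, emits the Cartesian product of its positives and
#' negatives, in deterministic lexicographic order (anchor, then positive,
#' then negative), so training runs are reproducible.
#'
#' @param sim Square similarity matrix with id dimnames.
#' @param config A [triplet_config()]; `anchors = "all"` uses every
#'   compound as an anchor.
#' @return Data frame with character columns `anchor`, `positive`,
#'   `negative` (possibly zero rows). Warns for anchors yielding no
#'   triplets.
#' @export
mine_triplets <- function(sim, config = triplet_config()) {
  ids <- rownames(sim)
  anchors <- if (identical(config$anchors, "all")) sort(ids) else {
    miss <- setdiff(config$anchors, ids)
    if (length(miss)) stop("unknown anchor id(s): ", paste(miss, collapse = ", "))
    sort(config$anchors)
  }
  parts <- lapply(anchors, function(a) {
    pn <- classify_compounds(a, sim, config)
    if (!length(pn$positives) || !length(pn$negatives)) {
      warning("anchor '", a, "' yields no triplets", call. = FALSE)
      return(NULL)
    }
    grid <- expand.grid(negative = pn$negatives, positive = pn$positives,
                        stringsAsFactors = FALSE)
    data.frame(anchor = a, positive = grid$positive,
               negative = grid$negative, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(anchor = character(0), positive = character(0),
                      negative = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$anchor, out$positive, out$negative), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export triplets as CSV
#'
#' @param triplets Data frame from [mine_triplets()].
#' @param path Output CSV path.
#' @export
write_triplets_csv <- function(triplets, path) {
  utils::write.csv(triplets, path, row.names = FALSE)
  invisible(path)
}
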