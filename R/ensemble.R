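# Per-residue fusion of several predictors' label tracks.
#
# Residues are combined independently: at each position the matched BPA of
# every predictor (given the label it emitted there) is folded with
# Dempster's rule, the fused mass is converted to probabilities with the
# pignistic transform, and the class with the highest probability wins.
# Ties are broken deterministically in the canonical order i, M, o. No
# positional smoothing is applied here; run-length grammar is enforced only
# later, when labels are decoded into a topology.

#' Construct a per-residue prediction track
#'
#' One predictor's (or the reference annotation's) label sequence for one
#' protein: a vector of `"i"`/`"M"`/`"o"`, one element per residue.
#'
#' @param sequence_id Protein identifier.
#' @param labels Character vector of single-letter labels over \{i, M, o\},
#'   or a single string which is split into characters.
#' @param predictor_id Label of the source predictor (or e.g. `"observed"`).
#' @return An object of class `"prediction_track"`: list with
#'   `sequence_id`, `predictor_id`, `labels`.
#' @export
#' @examples
#' prediction_track("p1", "iiMMMMMoo", "toy")
prediction_track <- function(sequence_id, labels, predictor_id = "predictor") {
  if (length(labels) == 1L && nchar(labels) > 1L)
    labels <- strsplit(labels, "")[[1L]]
  labels <- as.character(labels)
  if (length(labels) == 0L)
    stop("a prediction track must cover at least one residue", call. = FALSE)
  bad <- which(!labels %in% residue_classes())
  if (length(bad) > 0L)
    stop("track '", sequence_id, "' (", predictor_id, "): invalid label '",
         labels[bad[1L]], "' at position ", bad[1L], call. = FALSE)
  structure(list(sequence_id = as.character(sequence_id),
                 predictor_id = as.character(predictor_id),
                 labels = labels),
            class = "prediction_track")
}

#' @export
print.prediction_track <- function(x, ...) {
  cat(sprintf("Prediction track '%s' by '%s' (%d residues)\n %s\n",
              x$sequence_id, x$predictor_id, length(x$labels),
              paste(x$labels, collapse = "")))
  invisible(x)
}

#' Fuse the predictions of several predictors for one residue
#'
#' Looks up each predictor's matched BPA for the label it emitted, combines
#' them with Dempster's rule, applies the pignistic transformation, and
#' decides the class by the maximum pignistic probability (ties broken in
#' canonical order i, M, o).
#'
#' @param predicted_labels Named character vector: predictor id -> label.
#' @param profiles Named list of [build_profile()] results covering every
#'   predictor in `predicted_labels`.
#' @return A list of class `"combined_residue"` with elements `mass`
#'   (the fused `mass_function`), `betp` (pignistic probabilities over
#'   i, M, o) and `decided` (the winning class).
#' @export
#' @examples
#' cm <- confusion_matrix(rbind(c(80, 10, 10), c(10, 80, 10), c(10, 10, 80)))
#' pr <- list(A = build_profile(cm), B = build_profile(cm))
#' combine_residue(c(A = "M", B = "M"), pr)$decided
combine_residue <- function(predicted_labels, profiles) {
  if (length(predicted_labels) == 0L)
    stop("at least one predictor is required", call. = FALSE)
  ids <- names(predicted_labels)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("'predicted_labels' must be named by predictor id", call. = FALSE)
  missing <- setdiff(ids, names(profiles))
  if (length(missing) > 0L)
    stop("no profile for predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bpas <- lapply(ids, function(id)
    lookup_bpa(profiles[[id]], predicted_labels[[id]]))
  mass <- tryCatch(combine_many(bpas), error = function(e) {
    stop("total conflict between predictors [",
         paste(ids, collapse = ", "), "] with labels [",
         paste(predicted_labels, collapse = ", "), "]: ",
         conditionMessage(e), call. = FALSE)
  })
  betp <- pignistic(mass)
  # canonical-order tie-break; ties are detected within 1e-9 so that exactly
  # symmetric label patterns are not split by floating-point summation order
  decided <- residue_classes()[which(betp >= max(betp) - 1e-9)][1L]
  structure(list(mass = mass, betp = betp, decided = decided),
            class = "combined_residue")
}

#' Fuse several predictors' tracks for one protein
#'
#' Position-wise [combine_residue()] over tracks of equal length for the
#' same protein. Because the fused result depends only on the tuple of
#' labels emitted at a position, each distinct label pattern is combined
#' once and reused.
#'
#' @param tracks List of [prediction_track()] objects, all for the same
#'   `sequence_id` and of equal length, with distinct predictor ids.
#' @param profiles Named list of [build_profile()] results, one per
#'   predictor id in `tracks`.
#' @param ensemble_id Predictor id given to the output track.
#' @param details If `TRUE`, also return the per-residue
#'   `combined_residue` objects.
#' @param cache Optional environment memoizing fused label patterns, shared
#'   across proteins when the same profiles are reused (as
#'   [combine_dataset()] does); one is created per call when `NULL`.
#' @return A [prediction_track()] with the fused labels; if
#'   `details = TRUE`, a list with elements `track` and `residues`.
#' @export
combine_tracks <- function(tracks, profiles, ensemble_id = "ensemble",
                           details = FALSE, cache = NULL) {
  if (!is.list(tracks) || length(tracks) == 0L)
    stop("'tracks' must be a non-empty list of prediction tracks",
         call. = FALSE)
  stopifnot(all(vapply(tracks, inherits, logical(1), "prediction_track")))
  ids <- vapply(tracks, `[[`, character(1), "predictor_id")
  if (anyDuplicated(ids))
    stop("duplicate predictor ids in tracks: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seq_ids <- unique(vapply(tracks, `[[`, character(1), "sequence_id"))
  if (length(seq_ids) != 1L)
    stop("all tracks must describe the same sequence (got: ",
         paste(seq_ids, collapse = ", "), ")", call. = FALSE)
  lens <- vapply(tracks, function(t) length(t$labels), integer(1))
  if (length(unique(lens)) != 1L)
    stop("track length mismatch for '", seq_ids, "': ",
         paste(ids, lens, sep = "=", collapse = ", "), call. = FALSE)

  lab_mat <- do.call(rbind, lapply(tracks, `[[`, "labels")) # predictors x pos
  patterns <- apply(lab_mat, 2L, paste, collapse = "")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  per_pos <- lapply(patterns, function(pat) {
    if (!is.null(cache[[pat]])) return(cache[[pat]])
    labs <- stats::setNames(strsplit(pat, "")[[1L]], ids)
    res <- combine_residue(labs, profiles)
    cache[[pat]] <- res
    res
  })
  fused <- prediction_track(seq_ids,
                            vapply(per_pos, `[[`, character(1), "decided"),
                            ensemble_id)
  if (details) list(track = fused, residues = per_pos) else fused
}

#' Fuse tracks for a whole dataset
#'
#' Applies [combine_tracks()] to every protein: `track_sets` is a list
#' (one element per predictor) of lists of tracks indexed by sequence id.
#'
#' @param track_sets Named list: predictor id -> list of
#'   [prediction_track()]s (named by sequence id or in matching order).
#' @param profiles Named list of profiles, one per predictor.
#' @param ensemble_id Predictor id of the fused output.
#' @return List of fused [prediction_track()]s, named by sequence id.
#' @export
combine_dataset <- function(track_sets, profiles, ensemble_id = "ensemble") {
  stopifnot(is.list(track_sets), length(track_sets) >= 1L)
  track_sets <- lapply(track_sets, .index_by_sequence)
  ids <- Reduce(intersect, lapply(track_sets, names))
  if (length(ids) == 0L)
    stop("no sequence id common to all predictors", call. = FALSE)
  cache <- new.env(parent = emptyenv()) # one profile set -> shared patterns
  out <- lapply(ids, function(sid) {
    combine_tracks(lapply(track_sets, `[[`, sid), profiles, ensemble_id,
                   cache = cache)
  })
  stats::setNames(out, ids)
}

# name a list of tracks by sequence_id
.index_by_sequence <- function(tracks) {
  stats::setNames(tracks, vapply(tracks, `[[`, character(1), "sequence_id"))
}
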