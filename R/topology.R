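# Decoding per-residue labels into a topology model and comparing models.
#
# A topology is the ordered list of membrane-spanning segments plus the
# side of the membrane the N-terminus sits on. Decoding applies a minimum
# helix length: maximal runs of "M" at least `min_tm_length` residues long
# become segments, shorter runs are absorbed into the neighbouring loop so
# the residue count is preserved. The orientation is read off the first
# non-M label (the literal "location of the first residue" rule is
# undefined when a sequence starts inside the membrane).

#' Construct a topology model
#'
#' @param sequence_id Protein identifier.
#' @param n_term_side Side of the membrane of the N-terminus: `"in"`,
#'   `"out"`, or `NA` when undefined (no non-M residue).
#' @param segments Two-column matrix or data frame of 1-based inclusive
#'   `start`/`end` residue indices of the transmembrane segments, in
#'   increasing order; zero rows for a protein without predicted helices.
#' @param length Total residue count of the protein.
#' @return An object of class `"topology_model"`.
#' @export
topology_model <- function(sequence_id, n_term_side, segments, length) {
  segments <- matrix(as.integer(as.matrix(segments)), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  length <- as.integer(length)
  if (length < 1L) stop("'length' must be positive", call. = FALSE)
  if (nrow(segments) > 0L) {
    if (any(segments[, "start"] > segments[, "end"]) ||
        any(segments < 1L) || any(segments > length))
      stop("segments must satisfy 1 <= start <= end <= length", call. = FALSE)
    if (nrow(segments) > 1L &&
        any(segments[-1L, "start"] <= segments[-nrow(segments), "end"]))
      stop("segments must be strictly increasing and non-overlapping",
           call. = FALSE)
  }
  if (!is.na(n_term_side) && !n_term_side %in% c("in", "out"))
    stop("'n_term_side' must be \"in\", \"out\" or NA", call. = FALSE)
  structure(list(sequence_id = as.character(sequence_id),
                 n_term_side = n_term_side,
                 segments = segments,
                 length = length),
            class = "topology_model")
}

#' @export
print.topology_model <- function(x, ...) {
  segs <- if (nrow(x$segments) == 0L) "none" else
    paste(x$segments[, "start"], x$segments[, "end"], sep = "-",
          collapse = ", ")
  cat(sprintf("Topology '%s' (%d aa): N-terminus %s, TM segments: %s\n",
              x$sequence_id, x$length,
              if (is.na(x$n_term_side)) "undefined" else x$n_term_side, segs))
  invisible(x)
}

#' Decode a residue label sequence into a topology model
#'
#' Maximal runs of `"M"` with length at least `min_tm_length` become
#' transmembrane segments. Shorter M runs are relabelled to the loop class
#' immediately preceding them (the following loop class when the run sits at
#' the N-terminus), preserving the residue count. The N-terminal side is
#' `"in"` if the first non-M label (after suppression) is `"i"`, `"out"` if
#' it is `"o"`. An all-M sequence has no defined orientation: the segment is
#' still returned, `n_term_side` is `NA`, and a warning is raised.
#'
#' @param labels Character vector over \{i, M, o\} (or a single string), or
#'   a [prediction_track()].
#' @param min_tm_length Minimum helix length in residues; default 5.
#' @param sequence_id Identifier for the returned model (taken from the
#'   track when `labels` is one).
#' @return A [topology_model()].
#' @export
#' @examples
#' decode_labels("iiiMMMMMMMMMMoooo")            # one helix, N-terminus in
#' decode_labels("iMMoMMMMMMMii")                # 2-residue M run suppressed
decode_labels <- function(labels, min_tm_length = 5L, sequence_id = "seq") {
  if (inherits(labels, "prediction_track")) {
    sequence_id <- labels$sequence_id
    labels <- labels$labels
  }
  if (length(labels) == 1L && nchar(labels) > 1L)
    labels <- strsplit(labels, "")[[1L]]
  if (length(labels) == 0L)
    stop("empty label sequence", call. = FALSE)
  if (any(!labels %in% residue_classes()))
    stop("labels must be over {i, M, o}", call. = FALSE)
  if (length(min_tm_length) != 1L || min_tm_length < 1L)
    stop("'min_tm_length' must be a positive integer", call. = FALSE)

  n <- length(labels)
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  # suppress sub-threshold M runs left to right: each takes the class of the
  # residue before it (after earlier suppressions), or after it at position 1
  for (k in seq_along(runs$values)) {
    if (runs$values[k] == "M" && runs$lengths[k] < min_tm_length) {
      repl <- if (starts[k] > 1L) labels[starts[k] - 1L]
              else if (ends[k] < n) labels[ends[k] + 1L]
              else "M" # single sub-threshold all-M sequence: nothing to merge into
      labels[starts[k]:ends[k]] <- repl
    }
  }
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  tm <- runs$values == "M" & runs$lengths >= min_tm_length
  segments <- cbind(start = starts[tm], end = ends[tm])

  non_m <- labels[labels != "M"]
  if (length(non_m) == 0L) {
    warning("all-M sequence '", sequence_id,
            "': membrane orientation is undefined", call. = FALSE)
    side <- NA_character_
  } else {
    side <- if (non_m[1L] == "i") "in" else "out"
  }
  topology_model(sequence_id, side, segments, n)
}

#' Reconstruct residue labels from a topology model
#'
#' Inverse of [decode_labels()] for grammar-consistent topologies: segment
#' residues become `"M"`, loops alternate between the two sides starting
#' from `n_term_side`.
#'
#' @param topo A [topology_model()] with a defined `n_term_side` (required
#'   whenever any residue lies outside a segment).
#' @return Character vector of labels of length `topo$length`.
#' @export
labels_from_topology <- function(topo) {
  stopifnot(inherits(topo, "topology_model"))
  n <- topo$length
  segs <- topo$segments
  covered <- sum(segs[, "end"] - segs[, "start"] + 1L)
  if (covered < n && is.na(topo$n_term_side))
    stop("cannot place loop labels: n_term_side is undefined", call. = FALSE)
  loop_cycle <- if (identical(topo$n_term_side, "out")) c("o", "i") else c("i", "o")
  labels <- character(n)
  pos <- 1L
  side_idx <- 1L
  for (k in seq_len(nrow(segs))) {
    if (pos < segs[k, "start"]) {
      labels[pos:(segs[k, "start"] - 1L)] <- loop_cycle[side_idx]
    }
    # crossing the membrane flips the side even for back-to-back segments
    side_idx <- 3L - side_idx
    labels[segs[k, "start"]:segs[k, "end"]] <- "M"
    pos <- segs[k, "end"] + 1L
  }
  if (pos <= n) labels[pos:n] <- loop_cycle[side_idx]
  labels
}

# intersection length of two inclusive integer intervals
.overlap_len <- function(a_start, a_end, b_start, b_end) {
  max(0L, min(a_end, b_end) - max(a_start, b_start) + 1L)
}

#' Are two topologies the same?
#'
#' A predicted topology matches the observed one when both have the same
#' number of transmembrane segments, the k-th predicted segment overlaps the
#' k-th observed segment by at least `min_overlap` residues for every k, and
#' the N-terminal side agrees.
#'
#' @param predicted,observed [topology_model()] objects for the same protein.
#' @param min_overlap Minimum overlap in residues for two segments to count
#'   as the same helix; default 9.
#' @return `TRUE` or `FALSE`.
#' @export
same_topology <- function(predicted, observed, min_overlap = 9L) {
  stopifnot(inherits(predicted, "topology_model"),
            inherits(observed, "topology_model"))
  p <- predicted$segments
  o <- observed$segments
  if (nrow(p) != nrow(o)) return(FALSE)
  if (!identical(predicted$n_term_side, observed$n_term_side)) return(FALSE)
  for (k in seq_len(nrow(p))) {
    if (.overlap_len(p[k, 1L], p[k, 2L], o[k, 1L], o[k, 2L]) < min_overlap)
      return(FALSE)
  }
  TRUE
}
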