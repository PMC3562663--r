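# Readers and writers: FASTA sequences, FASTA-like per-residue label files,
# confusion-matrix TSVs, topology reports, and YAML run configs.
#
# All readers validate and reject rather than silently truncate; errors
# carry the file and the offending record or line. Files are UTF-8 with
# Unix newlines on write; CRLF is tolerated on read.

#' Read a FASTA file of protein sequences
#'
#' Standard FASTA parsing via Biostrings; multi-line sequences are
#' concatenated and the record id is the first whitespace-delimited token of
#' the header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(path, ": no FASTA records", call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(path, ": record with empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop(path, ": duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- as.character(set)
  if (any(!nzchar(seqs)))
    stop(path, ": empty sequence for id ", ids[!nzchar(seqs)][1L],
         call. = FALSE)
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector (names = ids).
#' @param path Output path.
#' @param width Line width for wrapping; default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (id in names(sequences)) {
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", id), substring(s, starts,
                                            pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read per-residue label tracks
#'
#' Label files are FASTA-like: a `>id` header, then lines of one character
#' per residue which are concatenated. Labels are validated against the
#' canonical alphabet \{i, M, o\} after applying an optional dialect map
#' (e.g. `c(H = "M", I = "i", O = "o")` for predictors emitting H/I/O), and
#' the track length must equal the corresponding sequence length.
#'
#' @param path Path to the label file.
#' @param sequences Named character vector of sequences (see
#'   [read_fasta()]); every label record id must occur here.
#' @param predictor_id Predictor id stored on the returned tracks; defaults
#'   to the file name without extension.
#' @param dialect Optional named character vector mapping foreign label
#'   characters to canonical ones.
#' @return Named list of [prediction_track()]s (names = sequence ids).
#' @export
read_labels <- function(path, sequences, predictor_id = NULL, dialect = NULL) {
  if (is.null(predictor_id))
    predictor_id <- sub("\\.[^.]*$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(path, ": no label records", call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(path, ": duplicate label record(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  labs <- as.character(set)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    if (!id %in% names(sequences))
      stop(path, ": label record '", id, "' has no sequence", call. = FALSE)
    s <- labs[k]
    if (!is.null(dialect)) {
      s <- chartr(paste(names(dialect), collapse = ""),
                  paste(dialect, collapse = ""), s)
    }
    if (nchar(s) != nchar(sequences[[id]]))
      stop(path, ": '", id, "' has ", nchar(s), " labels for ",
           nchar(sequences[[id]]), " residues", call. = FALSE)
    chars <- strsplit(s, "")[[1L]]
    bad <- which(!chars %in% residue_classes())
    if (length(bad) > 0L)
      stop(path, ": '", id, "': unknown label '", chars[bad[1L]],
           "' at position ", bad[1L], " (after dialect mapping)",
           call. = FALSE)
    out[[k]] <- prediction_track(id, chars, predictor_id)
  }
  stats::setNames(out, ids)
}

#' Write per-residue label tracks
#'
#' @param tracks List of [prediction_track()]s.
#' @param path Output path.
#' @param width Line width; default 60.
#' @return `path`, invisibly.
#' @export
write_labels <- function(tracks, path, width = 60L) {
  seqs <- vapply(tracks, function(t) paste(t$labels, collapse = ""),
                 character(1))
  names(seqs) <- vapply(tracks, `[[`, character(1), "sequence_id")
  write_fasta(seqs, path, width)
}

#' Read a confusion matrix from TSV
#'
#' The format mirrors the canonical table layout: a header line
#' `truth<TAB>i<TAB>M<TAB>o`, then three rows labelled `i`, `M`, `o` (true
#' class) holding integer counts of predicted classes.
#'
#' @param path Path to the TSV file.
#' @param predictor_id Predictor label; defaults to the file name without
#'   extension.
#' @return A [confusion_matrix()].
#' @export
read_confusion <- function(path, predictor_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(predictor_id))
    predictor_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) != 4L)
    stop(path, ": expected a header plus 3 rows, got ", length(lines),
         " non-empty lines", call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("truth", residue_classes())))
    stop(path, " line 1: header must be 'truth\\ti\\tM\\to'", call. = FALSE)
  counts <- matrix(0, 3L, 3L)
  for (r in 1:3) {
    cells <- strsplit(lines[r + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != 4L || cells[1L] != residue_classes()[r])
      stop(path, " line ", r + 1L, ": expected row label '",
           residue_classes()[r], "' and 3 counts", call. = FALSE)
    vals <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(vals) || any(vals != floor(vals)) || any(vals < 0))
      stop(path, " line ", r + 1L, ": counts must be non-negative integers",
           call. = FALSE)
    counts[r, ] <- vals
  }
  confusion_matrix(counts, predictor_id)
}

#' Write a confusion matrix to TSV
#'
#' @param cm A [confusion_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cls <- residue_classes()
  lines <- c(paste(c("truth", cls), collapse = "\t"),
             vapply(1:3, function(r)
               paste(c(cls[r], format(unclass(cm)[r, ], scientific = FALSE,
                                      trim = TRUE)),
                     collapse = "\t"), character(1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write topology models as a TSV report
#'
#' Columns: `sequence_id`, `n_term_side`, and the comma-separated
#' `start-end` segment list (empty when no segments).
#'
#' @param topologies List of [topology_model()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_report <- function(topologies, path) {
  rows <- vapply(topologies, function(t) {
    segs <- if (nrow(t$segments) == 0L) "" else
      paste(t$segments[, "start"], t$segments[, "end"], sep = "-",
            collapse = ",")
    paste(t$sequence_id,
          if (is.na(t$n_term_side)) "undefined" else t$n_term_side,
          segs, sep = "\t")
  }, character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("sequence_id\tn_term_side\tsegments", rows), con, sep = "\n")
  invisible(path)
}

#' Read a cross-validation / simulation run config (YAML)
#'
#' Expected keys: `fasta`, `observed`, `predictors` (map of id ->
#' \{labels, confusion?\}), and optional `n_folds`, `seed`,
#' `min_tm_length`, `min_overlap`, `out`.
#'
#' @param path Path to the YAML file.
#' @return Named list with defaults filled in (`n_folds = 10`, `seed = 1`,
#'   `min_tm_length = 5`, `min_overlap = 9`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(n_folds = 10L, seed = 1L, min_tm_length = 5L,
                   min_overlap = 9L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("min_tm_length", "min_overlap"))
    if (cfg[[k]] < 1L) stop("config '", k, "' must be positive", call. = FALSE)
  cfg
}

#' Published benchmark confusion matrices (MPtopo 125-protein set)
#'
#' Residue-level confusion matrices reported for five individual topology
#' predictors (OCTOPUS, PRO-TMHMM, PRODIV-TMHMM, SCAMPI-msa, SCAMPI-seq)
#' and for the evidential ensemble on a benchmark of 125 transmembrane
#' proteins derived from the MPtopo database, bundled as plain-text TSVs.
#'
#' @param predictor One of `"OCTOPUS"`, `"PRO"`, `"PRODIV"`,
#'   `"SCAMPI-msa"`, `"SCAMPI-seq"`, `"TOPPER"`; or `NULL` for all.
#' @return A [confusion_matrix()], or a named list of all six.
#' @export
#' @examples
#' recognition_rate(mptopo_confusion("OCTOPUS"))
mptopo_confusion <- function(predictor = NULL) {
  files <- c("OCTOPUS" = "octopus", "PRO" = "pro_tmhmm",
             "PRODIV" = "prodiv_tmhmm", "SCAMPI-msa" = "scampi_msa",
             "SCAMPI-seq" = "scampi_seq", "TOPPER" = "topper")
  if (is.null(predictor)) {
    out <- lapply(names(files), mptopo_confusion)
    return(stats::setNames(out, names(files)))
  }
  if (!predictor %in% names(files))
    stop("unknown predictor '", predictor, "'; choose one of: ",
         paste(names(files), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", "mptopo125",
                      paste0(files[[predictor]], "_confusion.tsv"),
                      package = "topper", mustWork = TRUE)
  read_confusion(path, predictor)
}

#' Published benchmark transmembrane-segment counts (MPtopo 125-protein set)
#'
#' Observed/predicted/correct segment totals (N_obs, N_prd, N_cor under the
#' 9-residue overlap rule) reported for the same predictors as
#' [mptopo_confusion()].
#'
#' @return Data frame with columns `predictor`, `n_obs`, `n_prd`, `n_cor`.
#' @export
mptopo_region_counts <- function() {
  path <- system.file("extdata", "mptopo125", "region_counts.tsv",
                      package = "topper", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
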