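# Synthetic benchmark generator.
#
# Ground-truth topologies follow the alternating loop/helix grammar of
# alpha-helical membrane proteins; predictor outputs are derived from the
# truth by per-residue class noise with known row-stochastic confusion
# probabilities, optionally after structural corruption (whole-helix
# deletion, boundary jitter). Everything is deterministic under a seed, so
# each pipeline stage can be tested against the known generating process
# without any external data.

#' Specification of a synthetic benchmark
#'
#' Defaults describe a benchmark at the scale of the 125-protein MPtopo
#' evaluation set: 125 proteins with 1-14 membrane-spanning helices of
#' 15-30 residues separated by loops of 1-60 residues (about 4 helices per
#' protein on average once short multi-spanning proteins are mixed in), and
#' five conditionally independent predictors each with 78% per-residue
#' accuracy.
#'
#' @param n_proteins Number of proteins.
#' @param n_helices Integer range `c(min, max)` of helices per protein.
#' @param helix_length Integer range of helix lengths (residues).
#' @param loop_length Integer range of loop lengths (residues).
#' @param predictors Named list of 3x3 row-stochastic matrices (rows =
#'   true class in order i, M, o): the per-residue label noise of each
#'   simulated predictor. Default: five predictors with 0.78 on the
#'   diagonal and the remainder split evenly.
#' @param deletion_prob Probability that a simulated predictor misses a
#'   whole helix (its residues relabelled to the flanking loop class).
#' @param jitter Maximum absolute shift, in residues, applied independently
#'   to each helix boundary before residue noise. 0 disables.
#' @param seed Integer seed.
#' @return A list of class `"sim_spec"`.
#' @export
sim_spec <- function(n_proteins = 125L,
                     n_helices = c(1L, 14L),
                     helix_length = c(15L, 30L),
                     loop_length = c(1L, 60L),
                     predictors = NULL,
                     deletion_prob = 0,
                     jitter = 0L,
                     seed = 1L) {
  if (is.null(predictors)) {
    base <- matrix((1 - 0.78) / 2, 3L, 3L)
    diag(base) <- 0.78
    predictors <- stats::setNames(rep(list(base), 5L), paste0("P", 1:5))
  }
  for (nm in names(predictors)) {
    pm <- predictors[[nm]]
    if (!is.matrix(pm) || !all(dim(pm) == c(3L, 3L)) || any(pm < 0) ||
        any(abs(rowSums(pm) - 1) > 1e-9))
      stop("predictor '", nm, "': confusion probabilities must be a 3x3 ",
           "row-stochastic matrix", call. = FALSE)
  }
  rng <- function(r, what) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L)
      stop("'", what, "' must be an increasing positive range", call. = FALSE)
    as.integer(r)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_helices = rng(n_helices, "n_helices"),
                 helix_length = rng(helix_length, "helix_length"),
                 loop_length = rng(loop_length, "loop_length"),
                 predictors = predictors,
                 deletion_prob = deletion_prob,
                 jitter = as.integer(jitter),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

.runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

#' Simulate ground-truth topologies
#'
#' Draws, per protein, a uniform N-terminal side, a helix count, helix and
#' loop lengths (all uniform over their ranges), assembles the alternating
#' loop/helix architecture, and emits a uniform-random amino-acid sequence
#' of matching length (sequence content plays no role downstream; only the
#' labels do).
#'
#' @param spec A [sim_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return List with `sequences` (named character vector), `observed`
#'   (named list of truth [prediction_track()]s) and `topologies` (named
#'   list of [topology_model()]s).
#' @export
simulate_truth <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$helix_length[1L] < 1L)
    stop("helices must be at least 1 residue long", call. = FALSE)
  .with_seed(seed, {
    ids <- sprintf("prot%03d", seq_len(spec$n_proteins))
    sequences <- character(spec$n_proteins)
    observed <- vector("list", spec$n_proteins)
    topologies <- vector("list", spec$n_proteins)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    for (k in seq_len(spec$n_proteins)) {
      side <- sample(c("in", "out"), 1L)
      h <- .runif_int(1L, spec$n_helices)
      hl <- .runif_int(h, spec$helix_length)
      ll <- .runif_int(h + 1L, spec$loop_length)
      loop_cycle <- if (side == "in") c("i", "o") else c("o", "i")
      labels <- character(0)
      segs <- matrix(integer(0), 0L, 2L)
      pos <- 0L
      for (j in seq_len(h)) {
        labels <- c(labels, rep(loop_cycle[(j - 1L) %% 2L + 1L], ll[j]))
        pos <- pos + ll[j]
        segs <- rbind(segs, c(pos + 1L, pos + hl[j]))
        labels <- c(labels, rep("M", hl[j]))
        pos <- pos + hl[j]
      }
      labels <- c(labels, rep(loop_cycle[h %% 2L + 1L], ll[h + 1L]))
      sequences[k] <- paste(sample(aa, length(labels), replace = TRUE),
                            collapse = "")
      observed[[k]] <- prediction_track(ids[k], labels, "observed")
      topologies[[k]] <- topology_model(ids[k], side, segs, length(labels))
    }
    names(sequences) <- ids
    list(sequences = sequences,
         observed = stats::setNames(observed, ids),
         topologies = stats::setNames(topologies, ids))
  })
}

#' Corrupt a truth track into a simulated predictor output
#'
#' Structural corruption first — each helix deleted with probability
#' `deletion_prob` (relabelled to the loop class before it, or after it at
#' the N-terminus), then each surviving helix boundary shifted by a uniform
#' integer in `[-jitter, jitter]` — followed by per-residue class noise:
#' each residue's output label is drawn from the confusion-probability row
#' of its (post-structural) label. With `jitter = 0` and `deletion_prob =
#' 0` the empirical confusion of output vs truth converges to
#' `confusion_probs`.
#'
#' @param truth A truth [prediction_track()].
#' @param confusion_probs 3x3 row-stochastic matrix (rows/cols in order
#'   i, M, o).
#' @param jitter,deletion_prob See [sim_spec()].
#' @param seed Integer seed.
#' @param predictor_id Id for the output track.
#' @return A [prediction_track()].
#' @export
corrupt_track <- function(truth, confusion_probs, jitter = 0L,
                          deletion_prob = 0, seed = 1L,
                          predictor_id = "sim") {
  stopifnot(inherits(truth, "prediction_track"))
  if (any(abs(rowSums(confusion_probs) - 1) > 1e-9) ||
      any(confusion_probs < 0))
    stop("'confusion_probs' rows must be non-negative and sum to 1",
         call. = FALSE)
  cls <- residue_classes()
  .with_seed(seed, {
    labels <- truth$labels
    n <- length(labels)
    if (deletion_prob > 0 || jitter > 0L) {
      runs <- rle(labels)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      helix <- which(runs$values == "M")
      for (k in helix) {
        if (deletion_prob > 0 && stats::runif(1L) < deletion_prob) {
          repl <- if (starts[k] > 1L) labels[starts[k] - 1L]
                  else if (ends[k] < n) labels[ends[k] + 1L] else "M"
          labels[starts[k]:ends[k]] <- repl
        } else if (jitter > 0L) {
          ds <- sample(seq.int(-jitter, jitter), 1L)
          de <- sample(seq.int(-jitter, jitter), 1L)
          s <- max(1L, starts[k] + ds)
          e <- min(n, ends[k] + de)
          if (s <= e) {
            left <- if (starts[k] > 1L) labels[starts[k] - 1L] else NULL
            right <- if (ends[k] < n) labels[ends[k] + 1L] else NULL
            labels[starts[k]:ends[k]] <-
              if (!is.null(left)) left else if (!is.null(right)) right else "M"
            labels[s:e] <- "M"
          }
        }
      }
    }
    u <- stats::runif(n)
    out <- character(n)
    for (p in 1:3) {
      sel <- labels == cls[p]
      if (!any(sel)) next
      cum <- cumsum(confusion_probs[p, ])
      out[sel] <- cls[findInterval(u[sel], cum, left.open = TRUE) + 1L]
    }
    prediction_track(truth$sequence_id, out, predictor_id)
  })
}

#' Simulate a complete benchmark bundle
#'
#' Composes [simulate_truth()] with one [corrupt_track()] pass per
#' simulated predictor. Optionally writes the bundle to disk through the
#' package's file formats: `sequences.fasta`, `observed.lab`, one
#' `<predictor>.lab` per predictor, and one `<predictor>_confusion.tsv`
#' holding the empirical confusion counts of that predictor against the
#' truth.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory, or `NULL` (default) to keep the bundle in
#'   memory only.
#' @param seed Seed; defaults to `spec$seed`.
#' @return List with `sequences`, `observed`, `topologies`,
#'   `predictor_tracks` (named list: predictor -> named list of tracks),
#'   `confusions` (empirical [confusion_matrix()] per predictor) and
#'   `spec`.
#' @export
simulate_dataset <- function(spec, dir = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  truth <- simulate_truth(spec, seed)
  sub_seeds <- .with_seed(seed + 1L,
                          sample.int(2147483646L, length(spec$predictors)))
  predictor_tracks <- vector("list", length(spec$predictors))
  names(predictor_tracks) <- names(spec$predictors)
  for (k in seq_along(spec$predictors)) {
    pid <- names(spec$predictors)[k]
    tracks <- vector("list", length(truth$observed))
    for (j in seq_along(truth$observed)) {
      tracks[[j]] <- corrupt_track(truth$observed[[j]],
                                   spec$predictors[[k]],
                                   jitter = spec$jitter,
                                   deletion_prob = spec$deletion_prob,
                                   seed = sub_seeds[k] %% 2100000000L + j,
                                   predictor_id = pid)
    }
    predictor_tracks[[k]] <- .index_by_sequence(tracks)
  }
  confusions <- lapply(names(predictor_tracks), function(pid)
    confusion_from_predictions(predictor_tracks[[pid]], truth$observed, pid))
  names(confusions) <- names(predictor_tracks)
  bundle <- c(truth, list(predictor_tracks = predictor_tracks,
                          confusions = confusions, spec = spec))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(bundle$sequences, file.path(dir, "sequences.fasta"))
    write_labels(bundle$observed, file.path(dir, "observed.lab"))
    for (pid in names(predictor_tracks)) {
      write_labels(predictor_tracks[[pid]], file.path(dir, paste0(pid, ".lab")))
      write_confusion(confusions[[pid]],
                      file.path(dir, paste0(pid, "_confusion.tsv")))
    }
  }
  bundle
}
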