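# Scoring at residue, transmembrane-segment, and topology level, plus the
# seeded cross-validation harness.
#
# Residue level: confusion matrix, per-class recall/precision/F and overall
# accuracy. Segment level: the Tusnady-Simon counts N_obs/N_prd/N_cor with
# M = N_cor/N_obs, C = N_cor/N_prd and the overall prediction power
# Q = sqrt(M*C) (geometric mean), a predicted and an observed segment
# counting as the same helix when they overlap by at least 9 residues.
# Topology level: fraction of proteins whose full topology (all segments
# matched one-to-one in order, equal counts, same N-terminal side) is
# correct.

#' Accumulate a confusion matrix from predicted vs observed tracks
#'
#' Counts residues over all proteins: cell (p, q) is the number of residues
#' whose true class is p and predicted class is q.
#'
#' @param predicted,observed Lists of [prediction_track()]s covering the
#'   same sequence ids with equal per-sequence lengths. Single tracks are
#'   accepted.
#' @param predictor_id Label for the resulting matrix; defaults to the
#'   (unique) predictor id of `predicted`.
#' @return A [confusion_matrix()].
#' @export
confusion_from_predictions <- function(predicted, observed,
                                       predictor_id = NULL) {
  if (inherits(predicted, "prediction_track")) predicted <- list(predicted)
  if (inherits(observed, "prediction_track")) observed <- list(observed)
  predicted <- .index_by_sequence(predicted)
  observed <- .index_by_sequence(observed)
  missing <- setdiff(names(predicted), names(observed))
  if (length(missing) > 0L)
    stop("no observed track for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(predictor_id)) {
    ids <- unique(vapply(predicted, `[[`, character(1), "predictor_id"))
    predictor_id <- if (length(ids) == 1L) ids else "predicted"
  }
  cls <- residue_classes()
  counts <- matrix(0, 3L, 3L)
  for (sid in names(predicted)) {
    p <- predicted[[sid]]$labels
    o <- observed[[sid]]$labels
    if (length(p) != length(o))
      stop("length mismatch for '", sid, "': predicted ", length(p),
           ", observed ", length(o), call. = FALSE)
    counts <- counts + table(factor(o, cls), factor(p, cls))
  }
  confusion_matrix(counts, predictor_id)
}

#' Residue-level metrics from a confusion matrix
#'
#' Per-class recall (diagonal over row sum), precision (diagonal over
#' column sum), F score `2PR/(P+R)`, and overall accuracy (trace over
#' total). A zero row or column makes the corresponding recall or precision
#' undefined (`NA`, distinct from 0); F is 0 when `P + R = 0` and `NA` when
#' either input is undefined.
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `"residue_metrics"`: list with `recall`,
#'   `precision`, `f_score` (named fractions over i, M, o) and `accuracy`.
#' @export
residue_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  x <- unclass(cm)
  if (sum(x) <= 0) stop("confusion matrix has no counts", call. = FALSE)
  rs <- rowSums(x); cs <- colSums(x); d <- diag(x)
  recall <- ifelse(rs > 0, d / rs, NA_real_)
  precision <- ifelse(cs > 0, d / cs, NA_real_)
  f <- ifelse(is.na(recall) | is.na(precision), NA_real_,
              ifelse(recall + precision > 0,
                     2 * precision * recall / (precision + recall), 0))
  cls <- residue_classes()
  structure(list(recall = stats::setNames(as.numeric(recall), cls),
                 precision = stats::setNames(as.numeric(precision), cls),
                 f_score = stats::setNames(as.numeric(f), cls),
                 accuracy = sum(d) / sum(x),
                 predictor_id = attr(cm, "predictor_id")),
            class = "residue_metrics")
}

#' Round half away from zero
#'
#' Report-style rounding (0.005 -> 0.01), as opposed to the IEEE
#' round-half-even of [round()]. Used wherever percentages are printed.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
#' @rdname residue_metrics
#' @param x A `residue_metrics` object.
#' @param ... Unused.
as.data.frame.residue_metrics <- function(x, ...) {
  data.frame(class = residue_classes(),
             recall_pct = round_half_up(100 * x$recall, 2L),
             precision_pct = round_half_up(100 * x$precision, 2L),
             f_score = round_half_up(x$f_score, 4L),
             accuracy_pct = round_half_up(100 * x$accuracy, 2L),
             row.names = NULL)
}

#' @export
print.residue_metrics <- function(x, ...) {
  cat("Residue-level metrics for '", x$predictor_id, "'\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Count correctly predicted transmembrane segments for one protein
#'
#' Greedy in-order one-to-one matching of predicted against observed
#' segments: walking both lists from the N-terminus, a pair overlapping by
#' at least `min_overlap` residues is matched and both segments are
#' consumed; otherwise the segment ending first is discarded. Each segment
#' is used at most once, so the count never exceeds either segment total.
#'
#' @param predicted,observed [topology_model()] objects for the same protein.
#' @param min_overlap Minimum overlap in residues; default 9.
#' @return Integer: this protein's contribution to N_cor.
#' @export
match_regions <- function(predicted, observed, min_overlap = 9L) {
  stopifnot(inherits(predicted, "topology_model"),
            inherits(observed, "topology_model"))
  p <- predicted$segments
  o <- observed$segments
  i <- 1L; j <- 1L; matched <- 0L
  while (i <= nrow(p) && j <= nrow(o)) {
    if (.overlap_len(p[i, 1L], p[i, 2L], o[j, 1L], o[j, 2L]) >= min_overlap) {
      matched <- matched + 1L
      i <- i + 1L; j <- j + 1L
    } else if (p[i, 2L] < o[j, 2L]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  matched
}

#' Segment-level prediction power from region counts
#'
#' `M = N_cor / N_obs` (fraction of real helices found), `C = N_cor /
#' N_prd` (fraction of predicted helices that are real), and the overall
#' prediction power `Q = sqrt(M * C)`, the geometric mean.
#'
#' @param n_obs,n_prd,n_cor Totals of observed, predicted, and correctly
#'   matched transmembrane segments.
#' @return Object of class `"region_score"`: list with the three counts and
#'   `m_frac`, `c_frac`, `q` as fractions (`NA` when a denominator is 0).
#' @export
#' @examples
#' region_score_from_counts(515, 507, 500) # Q just under 0.979
region_score_from_counts <- function(n_obs, n_prd, n_cor) {
  if (n_cor > min(n_obs, n_prd))
    stop("n_cor cannot exceed min(n_obs, n_prd)", call. = FALSE)
  m <- if (n_obs > 0) n_cor / n_obs else NA_real_
  cc <- if (n_prd > 0) n_cor / n_prd else NA_real_
  q <- if (is.na(m) || is.na(cc)) NA_real_ else sqrt(m * cc)
  structure(list(n_obs = as.integer(n_obs), n_prd = as.integer(n_prd),
                 n_cor = as.integer(n_cor),
                 m_frac = m, c_frac = cc, q = q),
            class = "region_score")
}

#' @export
print.region_score <- function(x, ...) {
  cat(sprintf(
    "TM segments: N_obs=%d N_prd=%d N_cor=%d | M=%.2f%% C=%.2f%% Q=%.2f%%\n",
    x$n_obs, x$n_prd, x$n_cor, 100 * x$m_frac, 100 * x$c_frac, 100 * x$q))
  invisible(x)
}

#' Segment-level scores over a set of proteins
#'
#' Sums observed, predicted, and matched segment counts over all
#' predicted/observed topology pairs and derives M, C, Q.
#'
#' @param pairs List of pairs: each element a list with components
#'   `predicted` and `observed`, both [topology_model()]s.
#' @param min_overlap Minimum overlap for [match_regions()]; default 9.
#' @return A [region_score_from_counts()] object.
#' @export
region_scores <- function(pairs, min_overlap = 9L) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  n_obs <- 0L; n_prd <- 0L; n_cor <- 0L
  for (pr in pairs) {
    n_obs <- n_obs + nrow(pr$observed$segments)
    n_prd <- n_prd + nrow(pr$predicted$segments)
    n_cor <- n_cor + match_regions(pr$predicted, pr$observed, min_overlap)
  }
  region_score_from_counts(n_obs, n_prd, n_cor)
}

#' Topology-level accuracy
#'
#' Fraction of proteins whose topology is entirely correct per
#' [same_topology()]: equal segment counts, every in-order pair overlapping
#' by at least `min_overlap` residues, and matching N-terminal side.
#'
#' @inheritParams region_scores
#' @return Fraction in `[0, 1]`.
#' @export
topology_accuracy <- function(pairs, min_overlap = 9L) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  mean(vapply(pairs, function(pr)
    same_topology(pr$predicted, pr$observed, min_overlap), logical(1)))
}

# run code under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# shuffle ids and cut into n_folds contiguous blocks of near-equal size
.assign_folds <- function(ids, n_folds, seed) {
  n <- length(ids)
  perm <- .with_seed(seed, sample.int(n))
  bounds <- floor(seq(0, n, length.out = n_folds + 1L))
  fold <- integer(n)
  for (f in seq_len(n_folds)) {
    fold[perm[(bounds[f] + 1L):bounds[f + 1L]]] <- f
  }
  stats::setNames(fold, ids)
}

#' Cross-validated evaluation of the evidential ensemble
#'
#' Splits the proteins into `n_folds` near-equal folds by a seeded shuffle.
#' For each fold, every predictor's confusion matrix — hence its evidence
#' profile — is estimated on the training folds only; the ensemble is then
#' applied to the held-out proteins. Residue, segment, and topology metrics
#' are pooled over all held-out predictions, for the ensemble and for each
#' individual predictor.
#'
#' @param observed List of reference [prediction_track()]s, one per protein.
#' @param predictor_tracks Named list: predictor id -> list of
#'   [prediction_track()]s covering the same proteins.
#' @param n_folds Number of folds; default 10.
#' @param seed Integer seed controlling the fold shuffle.
#' @param min_tm_length Minimum helix length used when decoding labels.
#' @param min_overlap Segment-overlap threshold; default 9.
#' @return List with `folds` (named fold assignment), `ensemble` and
#'   `predictors` (each: `confusion`, `metrics`, `regions`,
#'   `topology_accuracy`), and `fold_sizes`.
#' @export
crossvalidate <- function(observed, predictor_tracks, n_folds = 10L,
                          seed = 1L, min_tm_length = 5L, min_overlap = 9L) {
  observed <- .index_by_sequence(observed)
  ids <- names(observed)
  if (n_folds < 2L) stop("'n_folds' must be at least 2", call. = FALSE)
  if (length(ids) < n_folds)
    stop("fewer proteins (", length(ids), ") than folds (", n_folds, ")",
         call. = FALSE)
  predictor_tracks <- lapply(predictor_tracks, .index_by_sequence)
  for (pid in names(predictor_tracks)) {
    missing <- setdiff(ids, names(predictor_tracks[[pid]]))
    if (length(missing) > 0L)
      stop("predictor '", pid, "' lacks tracks for: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  folds <- .assign_folds(ids, n_folds, seed)
  obs_topo <- lapply(observed, decode_labels, min_tm_length = min_tm_length)

  fused_all <- list()
  for (f in seq_len(n_folds)) {
    test_ids <- ids[folds == f]
    train_ids <- ids[folds != f]
    profiles <- lapply(names(predictor_tracks), function(pid) {
      cm <- confusion_from_predictions(predictor_tracks[[pid]][train_ids],
                                       observed[train_ids], pid)
      build_profile(cm)
    })
    names(profiles) <- names(predictor_tracks)
    fused_all <- c(fused_all, combine_dataset(
      lapply(predictor_tracks, `[`, test_ids), profiles))
  }
  fused_all <- fused_all[ids]

  score_tracks <- function(tracks) {
    cm <- confusion_from_predictions(tracks, observed)
    pairs <- lapply(ids, function(sid) list(
      predicted = decode_labels(tracks[[sid]], min_tm_length),
      observed = obs_topo[[sid]]))
    list(confusion = cm,
         metrics = residue_metrics(cm),
         regions = region_scores(pairs, min_overlap),
         topology_accuracy = topology_accuracy(pairs, min_overlap))
  }

  list(folds = folds,
       fold_sizes = as.integer(table(folds)),
       ensemble = score_tracks(fused_all),
       predictors = lapply(predictor_tracks, score_tracks))
}
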