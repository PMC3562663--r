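# Basic probability assignments from predictor confusion matrices.
#
# A predictor's abstract-level output (a single class label per residue) is
# turned into evidence via its confusion matrix: when the predictor says
# class p, the evidence is a two-focal mass function putting the predictor's
# overall recognition rate Rc on {p} and the remainder 1 - Rc on the
# complementary doubleton (not on the full frame). The complement-mass
# choice follows Xu et al.'s abstract-level construction and changes
# combination behaviour relative to the "ignorance" variant.

#' Construct a confusion matrix
#'
#' A 3x3 table of residue counts, rows indexed by the true class and columns
#' by the predicted class, both in the canonical order (i, M, o).
#'
#' @param counts 3x3 numeric matrix of non-negative counts (rows = truth,
#'   columns = prediction). Row/column names, if present, must be
#'   `c("i","M","o")`.
#' @param predictor_id Label of the predictor the matrix describes.
#' @return An object of class `"confusion_matrix"`: the 3x3 matrix with
#'   dimnames `i/M/o`, carrying a `predictor_id` attribute.
#' @export
#' @examples
#' confusion_matrix(rbind(c(90, 5, 5), c(10, 85, 5), c(5, 5, 90)), "toy")
confusion_matrix <- function(counts, predictor_id = "predictor") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)))
    stop("a confusion matrix is 3x3 over (i, M, o)", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("confusion counts must be finite and non-negative", call. = FALSE)
  cls <- residue_classes()
  if (!is.null(rownames(counts)) && !identical(rownames(counts), cls))
    stop("rows must be the true classes in order i, M, o", call. = FALSE)
  if (!is.null(colnames(counts)) && !identical(colnames(counts), cls))
    stop("columns must be the predicted classes in order i, M, o",
         call. = FALSE)
  dimnames(counts) <- list(truth = cls, predicted = cls)
  structure(counts, class = "confusion_matrix", predictor_id = predictor_id)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix for predictor '", attr(x, "predictor_id"),
      "' (rows = truth, cols = predicted)\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Overall recognition rate of a predictor
#'
#' The trace of the confusion matrix over its grand total: the fraction of
#' residues assigned their true class.
#'
#' @param cm A [confusion_matrix()].
#' @return A fraction in `[0, 1]`.
#' @export
recognition_rate <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no counts", call. = FALSE)
  sum(diag(unclass(cm))) / total
}

#' Add a pseudocount to every cell of a confusion matrix
#'
#' Laplace-style smoothing guard against degenerate recognition rates of
#' exactly 0 or 1, which yield categorical BPAs and can make Dempster's rule
#' inapplicable (total conflict). Off (`pseudocount = 0`) by default.
#'
#' @param cm A [confusion_matrix()].
#' @param pseudocount Non-negative number added to each of the 9 cells.
#' @return A smoothed [confusion_matrix()].
#' @export
smooth_matrix <- function(cm, pseudocount = 0) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (length(pseudocount) != 1L || !is.finite(pseudocount) || pseudocount < 0)
    stop("'pseudocount' must be a single non-negative number", call. = FALSE)
  confusion_matrix(unclass(cm) + pseudocount, attr(cm, "predictor_id"))
}

#' Build a predictor's evidence profile from its confusion matrix
#'
#' For each class p the profile holds the mass function used whenever the
#' predictor outputs p: mass `Rc` on the singleton \{p\} and `1 - Rc` on the
#' complementary pair of classes, where `Rc` is the predictor's overall
#' [recognition_rate()]. A single global rate is used for all three classes.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `"predictor_profile"`: list with
#'   `predictor_id`, `recognition_rate`, and `bpas` (one `mass_function`
#'   per class, named `i`, `M`, `o`).
#' @export
#' @examples
#' cm <- confusion_matrix(rbind(c(80, 10, 10), c(10, 80, 10), c(10, 10, 80)))
#' build_profile(cm)$recognition_rate # 0.8
build_profile <- function(cm) {
  rc <- recognition_rate(cm)
  cls <- residue_classes()
  bpas <- lapply(cls, function(p) {
    comp <- paste(setdiff(cls, p), collapse = "")
    if (rc >= 1) {
      mass_function(stats::setNames(1, p))
    } else if (rc <= 0) {
      mass_function(stats::setNames(1, comp))
    } else {
      mass_function(stats::setNames(c(rc, 1 - rc), c(p, comp)))
    }
  })
  names(bpas) <- cls
  structure(list(predictor_id = attr(cm, "predictor_id"),
                 recognition_rate = rc, bpas = bpas),
            class = "predictor_profile")
}

#' @export
print.predictor_profile <- function(x, ...) {
  cat(sprintf("Predictor profile '%s': recognition rate %.4f\n",
              x$predictor_id, x$recognition_rate))
  invisible(x)
}

#' Look up the matched BPA for a predicted label
#'
#' Pure lookup of the class-conditioned mass function a predictor's label
#' contributes to the per-residue fusion.
#'
#' @param profile A [build_profile()] result.
#' @param predicted A single class label, one of `"i"`, `"M"`, `"o"`.
#' @return A `mass_function`.
#' @export
lookup_bpa <- function(profile, predicted) {
  stopifnot(inherits(profile, "predictor_profile"))
  if (length(predicted) != 1L || !predicted %in% residue_classes())
    stop("predicted label must be one of i, M, o (got '",
         paste(predicted, collapse = ","), "'); map dialect labels first",
         call. = FALSE)
  profile$bpas[[predicted]]
}
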