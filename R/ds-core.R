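# Dempster-Shafer algebra over the fixed three-class residue frame.
#
# The frame of discernment is Omega = {i, M, o}: intracellular loop,
# membrane-spanning (transmembrane) residue, extracellular loop. Subsets of
# the frame are written as strings of class letters in the fixed canonical
# order i < M < o ("i", "Mo", "iMo", ...); this order is used everywhere a
# layout or a tie-break is needed, so results are bit-reproducible.

#' Residue classes of the topology frame
#'
#' The three per-residue classes used throughout the package, in the
#' canonical order: `"i"` (intracellular), `"M"` (transmembrane helix),
#' `"o"` (extracellular). All matrices, label strings and tie-breaks use
#' this order.
#'
#' @return Character vector `c("i", "M", "o")`.
#' @export
#' @examples
#' residue_classes()
residue_classes <- function() c("i", "M", "o")

# bitmask of each class in the canonical order: i=1, M=2, o=4
.class_bit <- c(i = 1L, M = 2L, o = 4L)

# subset key string for each mask 1..7 (mask 0 = empty set has no key)
.mask_key <- c("i", "M", "iM", "o", "io", "Mo", "iMo")

# Canonicalize a proposition given as a character vector of members or a
# single string of class letters; returns its bitmask (0 for the empty set).
.prop_mask <- function(A) {
  if (length(A) == 1L && is.character(A)) A <- strsplit(A, "")[[1L]]
  if (length(A) == 0L) return(0L)
  bits <- .class_bit[A]
  if (anyNA(bits)) {
    stop("unknown residue class in proposition: ",
         paste(unique(A[is.na(bits)]), collapse = ", "),
         " (classes are i, M, o)", call. = FALSE)
  }
  Reduce(bitwOr, unique(bits))
}

.mask_size <- function(mask) {
  # population count for masks 0..7
  c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L)[mask + 1L]
}

#' Construct a mass function (basic probability assignment)
#'
#' A mass function assigns non-negative mass to subsets of the frame
#' \{i, M, o\}, with zero mass on the empty set and total mass one. Subsets
#' are named by their member letters, e.g. `"M"` or `"io"`; member order in
#' the input is irrelevant, keys are canonicalized to the order i, M, o.
#'
#' @param masses Named numeric vector; names are subset strings over
#'   \{i, M, o\}, values are masses in `[0, 1]`.
#' @param tol Tolerance on `|sum(masses) - 1|`; default `1e-9`.
#' @return An object of class `"mass_function"`: a named numeric vector over
#'   the focal elements (zero-mass entries are dropped), in canonical subset
#'   order.
#' @export
#' @examples
#' mass_function(c(M = 0.7869, io = 0.2131))
#' vacuous_mass() # total ignorance: all mass on the full frame
mass_function <- function(masses, tol = 1e-9) {
  if (length(masses) == 0L || !is.numeric(masses) || is.null(names(masses)))
    stop("'masses' must be a non-empty named numeric vector", call. = FALSE)
  if (any(masses < 0)) stop("masses must be non-negative", call. = FALSE)
  keys <- names(masses)
  masks <- vapply(keys, .prop_mask, integer(1))
  if (any(masks == 0L & masses > 0))
    stop("the empty set cannot carry mass", call. = FALSE)
  if (abs(sum(masses) - 1) > tol)
    stop(sprintf("masses must sum to 1 (got %.12f)", sum(masses)),
         call. = FALSE)
  full <- numeric(7L)
  for (k in seq_along(masks)) {
    if (masks[k] > 0L) full[masks[k]] <- full[masks[k]] + masses[k]
  }
  .mass_from_full(full)
}

# internal: build a validated mass_function from a length-7 mask-indexed
# vector, renormalizing to absorb floating-point drift
.mass_from_full <- function(full) {
  full <- full / sum(full)
  focal <- which(full > 0)
  out <- full[focal]
  names(out) <- .mask_key[focal]
  class(out) <- "mass_function"
  out
}

# internal: mask-indexed length-7 vector of a mass_function
.mass_full <- function(m) {
  full <- numeric(7L)
  full[vapply(names(m), .prop_mask, integer(1))] <- unclass(m)
  full
}

#' @export
print.mass_function <- function(x, ...) {
  cat("Mass function on {i, M, o}\n")
  for (k in seq_along(x)) cat(sprintf("  m({%s}) = %.6g\n", names(x)[k], x[k]))
  invisible(x)
}

#' The vacuous mass function
#'
#' Total ignorance: all mass on the full frame \{i, M, o\}. It is the
#' neutral element of Dempster's rule.
#'
#' @return A `mass_function`.
#' @export
vacuous_mass <- function() mass_function(c(iMo = 1))

#' Belief and plausibility of a proposition
#'
#' `belief()` sums the mass of all focal elements contained in `A` (the
#' lower bound on the probability of `A`); `plausibility()` sums the mass of
#' all focal elements intersecting `A` (the upper bound), and equals
#' `1 - belief(complement of A)`.
#'
#' @param m A `mass_function`.
#' @param A Proposition: a character vector of classes or a subset string,
#'   e.g. `"Mo"` or `c("M", "o")`.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' m <- mass_function(c(M = 0.9, io = 0.1))
#' belief(m, "Mo")       # 0.9
#' plausibility(m, "i")  # 0.1
belief <- function(m, A) {
  stopifnot(inherits(m, "mass_function"))
  a <- .prop_mask(A)
  masks <- vapply(names(m), .prop_mask, integer(1))
  sum(m[bitwAnd(masks, a) == masks])
}

#' @rdname belief
#' @export
plausibility <- function(m, A) {
  stopifnot(inherits(m, "mass_function"))
  a <- .prop_mask(A)
  masks <- vapply(names(m), .prop_mask, integer(1))
  sum(m[bitwAnd(masks, a) != 0L])
}

#' Combine two mass functions with Dempster's rule
#'
#' The orthogonal sum: for every non-empty subset A, the combined mass is
#' `sum over B, C with B intersect C = A of m1(B) m2(C)`, renormalized by
#' `1 - K` where the conflict `K` is the total product mass falling on the
#' empty intersection. The rule requires `K < 1`; totally conflicting
#' evidence (e.g. two opposed categorical masses) raises an error.
#'
#' @param m1,m2 `mass_function` objects.
#' @return The combined `mass_function`.
#' @export
#' @examples
#' a <- mass_function(c(M = 0.8, io = 0.2))
#' b <- mass_function(c(M = 0.7, io = 0.3))
#' combine_dempster(a, b) # reinforced mass on {M}
combine_dempster <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  f1 <- .mass_full(m1)
  f2 <- .mass_full(m2)
  out <- numeric(7L)
  conflict <- 0
  for (b in which(f1 > 0)) {
    for (cc in which(f2 > 0)) {
      a <- bitwAnd(b, cc)
      w <- f1[b] * f2[cc]
      if (a == 0L) conflict <- conflict + w else out[a] <- out[a] + w
    }
  }
  if (conflict >= 1 - 1e-12)
    stop("total conflict (K = ", format(conflict),
         "): Dempster's rule requires K < 1", call. = FALSE)
  .mass_from_full(out / (1 - conflict))
}

#' Combine a list of mass functions
#'
#' Left fold of [combine_dempster()]; the orthogonal sum is commutative and
#' associative, so the result does not depend on the order of the list (up
#' to floating-point drift absorbed by per-step renormalization).
#'
#' @param ms Non-empty list of `mass_function` objects.
#' @return The combined `mass_function`.
#' @export
combine_many <- function(ms) {
  if (!is.list(ms) || length(ms) == 0L)
    stop("'ms' must be a non-empty list of mass functions", call. = FALSE)
  out <- ms[[1L]]
  stopifnot(inherits(out, "mass_function"))
  if (length(ms) > 1L) {
    for (k in 2L:length(ms)) {
      out <- tryCatch(combine_dempster(out, ms[[k]]), error = function(e) {
        stop("total conflict while combining element ", k, " of ", length(ms),
             ": ", conditionMessage(e), call. = FALSE)
      })
    }
  }
  out
}

#' Pignistic probability transformation
#'
#' Converts a mass function into a probability distribution over the three
#' residue classes by splitting the mass of each focal element equally among
#' its members: `BetP(x) = sum over A containing x of m(A) / |A|`. This is
#' the decision-level transform of the transferable belief model; the fused
#' per-residue class is the argmax of `BetP`.
#'
#' @param m A `mass_function`.
#' @return Named numeric vector of probabilities over `c("i", "M", "o")`,
#'   summing to 1.
#' @export
#' @examples
#' pignistic(vacuous_mass())                         # uniform 1/3
#' pignistic(mass_function(c(M = 0.6, io = 0.4)))    # (0.2, 0.6, 0.2)
pignistic <- function(m) {
  stopifnot(inherits(m, "mass_function"))
  betp <- c(i = 0, M = 0, o = 0)
  masks <- vapply(names(m), .prop_mask, integer(1))
  sizes <- .mask_size(masks)
  for (k in seq_along(m)) {
    share <- m[[k]] / sizes[k]
    for (cl in residue_classes()) {
      if (bitwAnd(masks[k], .class_bit[[cl]]) != 0L)
        betp[cl] <- betp[cl] + share
    }
  }
  betp / sum(betp)
}

#' Serialize a mass function to JSON
#'
#' Debug representation: an object mapping subset strings to masses, e.g.
#' `{"M": 0.7869, "io": 0.2131}`.
#'
#' @param m A `mass_function`.
#' @return A JSON string.
#' @export
mass_to_json <- function(m) {
  stopifnot(inherits(m, "mass_function"))
  jsonlite::toJSON(as.list(unclass(m)), auto_unbox = TRUE, digits = NA)
}
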