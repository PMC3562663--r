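# Independent brute-force reference implementations, deliberately naive:
# subsets are plain character vectors of class members, and Dempster's rule
# is evaluated by looping over all 8 x 8 subset pairs of the power set,
# including non-focal ones. Nothing here touches the package's bitmask
# representation.

oracle_classes <- c("i", "M", "o")

# the full power set of {i, M, o} as member vectors, empty set first
oracle_power_set <- local({
  out <- list(character(0))
  for (cl in oracle_classes) {
    out <- c(out, lapply(out, function(s) c(s, cl)))
  }
  out
})

oracle_key <- function(members) {
  paste(oracle_classes[oracle_classes %in% members], collapse = "")
}

# named mass vector (canonical keys) -> length-8 vector over the power set
oracle_expand <- function(m) {
  keys <- vapply(oracle_power_set, oracle_key, character(1))
  full <- stats::setNames(numeric(8L), keys)
  full[names(m)] <- as.numeric(m)
  full
}

oracle_collapse <- function(full) {
  focal <- full[full > 0 & nzchar(names(full))]
  focal / sum(focal)
}

# Dempster's orthogonal sum by exhaustive enumeration
oracle_combine <- function(m1, m2) {
  f1 <- oracle_expand(m1)
  f2 <- oracle_expand(m2)
  keys <- names(f1)
  out <- stats::setNames(numeric(8L), keys)
  conflict <- 0
  for (b in seq_along(oracle_power_set)) {
    for (cc in seq_along(oracle_power_set)) {
      w <- f1[b] * f2[cc]
      if (w == 0) next
      inter <- intersect(oracle_power_set[[b]], oracle_power_set[[cc]])
      if (length(inter) == 0L) conflict <- conflict + w
      else out[oracle_key(inter)] <- out[oracle_key(inter)] + w
    }
  }
  if (conflict >= 1 - 1e-12) stop("oracle: total conflict")
  oracle_collapse(out / (1 - conflict))
}

oracle_pignistic <- function(m) {
  betp <- stats::setNames(numeric(3L), oracle_classes)
  for (k in seq_along(m)) {
    members <- strsplit(names(m)[k], "")[[1L]]
    for (cl in members) betp[cl] <- betp[cl] + m[[k]] / length(members)
  }
  betp
}

# the two-focal evidence a predictor with recognition rate rc contributes
# when it outputs class cl, as a plain named vector
oracle_predictor_mass <- function(cl, rc) {
  comp <- oracle_key(setdiff(oracle_classes, cl))
  if (rc >= 1) stats::setNames(1, cl)
  else if (rc <= 0) stats::setNames(1, comp)
  else stats::setNames(c(rc, 1 - rc), c(cl, comp))
}

# brute-force fused decision for a vector of labels and matching rc values
oracle_decide <- function(labels, rcs) {
  m <- oracle_predictor_mass(labels[1L], rcs[1L])
  for (k in seq_along(labels)[-1L]) {
    m <- oracle_combine(m, oracle_predictor_mass(labels[k], rcs[k]))
  }
  betp <- oracle_pignistic(m)
  # same tolerance-aware canonical tie-break as the production decision
  oracle_classes[which(betp >= max(betp) - 1e-9)][1L]
}

# random valid BPA over 2-4 random non-empty focal subsets
random_bpa <- function() {
  keys <- vapply(oracle_power_set[-1L], oracle_key, character(1))
  picked <- sample(keys, sample(2:4, 1L))
  w <- stats::runif(length(picked))
  mass_function(stats::setNames(w / sum(w), picked))
}

# a random grammar-consistent topology model for round-trip tests
random_topology <- function(id = "t", min_helix = 9L) {
  h <- sample(0:4, 1L)
  segs <- matrix(integer(0), 0L, 2L)
  pos <- 0L
  for (j in seq_len(h)) {
    pos <- pos + sample(1:20, 1L)          # loop before the helix
    len <- min_helix + sample(0:15, 1L)
    segs <- rbind(segs, c(pos + 1L, pos + len))
    pos <- pos + len
  }
  pos <- pos + sample(1:20, 1L)            # trailing loop
  topology_model(id, sample(c("in", "out"), 1L), segs, pos)
}
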