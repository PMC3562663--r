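# Dempster-Shafer core: mass functions, Bel/Pl, combination, pignistic.

test_that("mass function construction validates and canonicalizes", {
  expect_s3_class(vacuous_mass(), "mass_function")
  m <- mass_function(c(M = 0.7869, io = 0.2131))
  expect_equal(sum(m), 1)
  expect_setequal(names(m), c("M", "io"))
  # member order in subset keys is canonicalized
  expect_equal(unname(mass_function(c(oi = 0.3, M = 0.7))[["io"]]), 0.3)
  # zero-mass entries are dropped
  expect_false("i" %in% names(mass_function(c(i = 0, iMo = 1))))

  expect_error(mass_function(stats::setNames(c(0.5, 0.5), c("M", ""))),
               "empty set")
  expect_error(mass_function(c(M = 0.5, io = 0.4)), "sum to 1")
  expect_error(mass_function(c(M = 1.2, io = -0.2)), "non-negative")
  expect_error(mass_function(c(x = 1)), "unknown residue class")
})

test_that("belief and plausibility enumerate focal elements correctly", {
  m <- mass_function(c(M = 0.9, io = 0.1))
  expect_equal(belief(m, "iMo"), 1)
  expect_equal(belief(m, "i"), 0)
  expect_equal(belief(m, "Mo"), 0.9)
  expect_equal(plausibility(m, "iMo"), 1)
  expect_equal(plausibility(m, "i"), 0.1)
  # propositions may be given as member vectors
  expect_equal(belief(m, c("o", "M")), 0.9)
})

test_that("Bel <= Pl and Pl(A) = 1 - Bel(complement) for random BPAs", {
  set.seed(42)
  subsets <- c("i", "M", "o", "iM", "io", "Mo", "iMo")
  for (rep in 1:50) {
    m <- random_bpa()
    for (A in subsets) {
      comp <- paste(setdiff(residue_classes(), strsplit(A, "")[[1]]),
                    collapse = "")
      expect_gte(plausibility(m, A), belief(m, A) - 1e-12)
      expect_equal(plausibility(m, A),
                   1 - (if (nzchar(comp)) belief(m, comp) else 0))
    }
  }
})

test_that("Dempster combination matches hand-enumerated cases", {
  # two agreeing two-focal BPAs: K = 0.8*0.3... enumerate the 4 pairs
  m1 <- mass_function(c(M = 0.8, io = 0.2))
  m2 <- mass_function(c(M = 0.7, io = 0.3))
  cmb <- combine_dempster(m1, m2)
  expect_equal(cmb[["M"]], 0.56 / 0.62, tolerance = 1e-12)
  expect_equal(cmb[["io"]], 0.06 / 0.62, tolerance = 1e-12)

  # conflicting singleton/doubleton structure, K = 0.56
  m3 <- mass_function(c(i = 0.8, Mo = 0.2))
  cmb2 <- combine_dempster(m3, m2)
  expect_equal(cmb2[["i"]], 6 / 11, tolerance = 1e-12)
  expect_equal(cmb2[["M"]], 7 / 22, tolerance = 1e-12)
  expect_equal(cmb2[["o"]], 3 / 22, tolerance = 1e-12)

  # the vacuous mass function is the neutral element
  id <- combine_dempster(m1, vacuous_mass())
  expect_equal(as.numeric(id[names(m1)]), as.numeric(m1), tolerance = 1e-12)

  # totally conflicting categorical evidence is rejected
  expect_error(combine_dempster(mass_function(c(i = 1)),
                                mass_function(c(M = 1))),
               "total conflict")
})

test_that("combination is commutative and associative", {
  set.seed(7)
  for (rep in 1:30) {
    a <- random_bpa(); b <- random_bpa(); cc <- random_bpa()
    ab <- combine_dempster(a, b)
    ba <- combine_dempster(b, a)
    expect_equal(ab[names(ba)], ba, tolerance = 1e-9)
    l <- combine_dempster(combine_dempster(a, b), cc)
    r <- combine_dempster(a, combine_dempster(b, cc))
    expect_equal(l[names(r)], r, tolerance = 1e-9)
  }
})

test_that("combine_many folds correctly and is order independent", {
  m <- mass_function(c(M = 0.8, io = 0.2))
  expect_identical(combine_many(list(m)), m)

  set.seed(11)
  ms <- replicate(4, random_bpa(), simplify = FALSE)
  ref <- combine_many(ms)
  perm <- combine_many(ms[c(3, 1, 4, 2)])
  expect_equal(ref[names(perm)], perm, tolerance = 1e-9)

  # repeated agreeing evidence reinforces the shared singleton
  prev <- m
  for (k in 2:5) {
    cur <- combine_many(rep(list(m), k))
    expect_gt(cur[["M"]], prev[["M"]])
    prev <- cur
  }
  expect_gt(combine_many(rep(list(m), 5))[["M"]], 0.8)

  expect_error(combine_many(list()), "non-empty")
  expect_error(
    combine_many(list(mass_function(c(i = 1)), mass_function(c(M = 1)))),
    "element 2")
})

test_that("pignistic transformation splits masses over members", {
  expect_equal(pignistic(vacuous_mass()),
               c(i = 1, M = 1, o = 1) / 3, tolerance = 1e-12)
  sing <- mass_function(c(i = 0.2, M = 0.5, o = 0.3))
  expect_equal(pignistic(sing), c(i = 0.2, M = 0.5, o = 0.3),
               tolerance = 1e-12)
  expect_equal(pignistic(mass_function(c(M = 0.6, io = 0.4))),
               c(i = 0.2, M = 0.6, o = 0.2), tolerance = 1e-12)
})

test_that("pignistic output is a distribution between Bel and Pl", {
  set.seed(5)
  for (rep in 1:50) {
    m <- random_bpa()
    betp <- pignistic(m)
    expect_equal(sum(betp), 1, tolerance = 1e-9)
    expect_true(all(betp >= 0))
    for (cl in residue_classes()) {
      expect_gte(betp[[cl]], belief(m, cl) - 1e-12)
      expect_lte(betp[[cl]], plausibility(m, cl) + 1e-12)
    }
    # agrees with the naive per-subset oracle
    expect_equal(betp, oracle_pignistic(unclass(m)), tolerance = 1e-12)
  }
})

test_that("production combination agrees with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:200) {
    a <- random_bpa(); b <- random_bpa()
    got <- combine_dempster(a, b)
    want <- oracle_combine(unclass(a), unclass(b))
    expect_equal(unclass(got)[names(want)], want, tolerance = 1e-12)
  }
})

test_that("mass functions serialize to subset-keyed JSON", {
  m <- mass_function(c(M = 0.75, io = 0.25))
  parsed <- jsonlite::fromJSON(mass_to_json(m))
  expect_equal(parsed$M, 0.75)
  expect_equal(parsed$io, 0.25)
})
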