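# Residue, segment, and topology scoring; cross-validation harness.

test_that("confusion accumulation counts truth rows vs predicted columns", {
  obs <- prediction_track("p1", "iM", "observed")
  prd <- prediction_track("p1", "Mo", "pred")
  cm <- confusion_from_predictions(prd, obs)
  want <- matrix(0, 3, 3); want[1, 2] <- 1; want[2, 3] <- 1
  expect_equal(unclass(cm), want, ignore_attr = TRUE)

  # identical tracks give a diagonal matrix with class totals
  t1 <- prediction_track("p1", "iiMMMoo", "x")
  cm2 <- confusion_from_predictions(t1, prediction_track("p1", "iiMMMoo", "observed"))
  expect_equal(unclass(cm2), diag(c(2, 3, 2)), ignore_attr = TRUE)

  expect_error(confusion_from_predictions(
    prediction_track("p1", "iM", "x"), prediction_track("p1", "iMo", "observed")),
    "length mismatch")
  expect_error(confusion_from_predictions(
    prediction_track("p2", "iM", "x"), prediction_track("p1", "iM", "observed")),
    "no observed track")
})

test_that("residue metrics reproduce the benchmark ensemble row", {
  met <- residue_metrics(mptopo_confusion("TOPPER"))
  df <- as.data.frame(met)
  expect_equal(df$recall_pct, c(85.96, 74.82, 81.85))
  expect_equal(df$precision_pct, c(73.77, 91.81, 72.98))
  expect_equal(df$f_score, c(0.7940, 0.8245, 0.7716))
  # the matrix trace gives 23918/29902 = 79.99% at 2 decimals
  expect_equal(df$accuracy_pct[1], 79.99)

  idm <- residue_metrics(confusion_matrix(diag(c(4, 5, 6))))
  expect_equal(unname(idm$recall), rep(1, 3))
  expect_equal(unname(idm$precision), rep(1, 3))
  expect_equal(unname(idm$f_score), rep(1, 3))
  expect_equal(idm$accuracy, 1)
})

test_that("zero rows or columns yield undefined, not zero, metrics", {
  cm <- confusion_matrix(rbind(c(5, 1, 0), c(0, 0, 0), c(2, 0, 3)))
  met <- residue_metrics(cm)
  expect_true(is.na(met$recall[["M"]]))   # no true M residues
  expect_true(is.na(met$precision[["o"]]) == FALSE)
  cm2 <- confusion_matrix(rbind(c(5, 1, 1), c(3, 0, 4), c(2, 0, 3)))
  met2 <- residue_metrics(cm2)
  expect_true(is.na(met2$precision[["M"]]) == FALSE) # column sum 1, defined
  cm3 <- confusion_matrix(rbind(c(5, 0, 2), c(3, 0, 4), c(2, 0, 3)))
  expect_true(is.na(residue_metrics(cm3)$precision[["M"]])) # empty column
})

test_that("segment matching honors the 9-residue overlap boundary", {
  obs <- topology_model("p", "in", cbind(10, 30), 60)
  expect_equal(match_regions(topology_model("p", "in", cbind(22, 45), 60),
                             obs), 1L)
  expect_equal(match_regions(topology_model("p", "in", cbind(23, 45), 60),
                             obs), 0L)
})

test_that("segment matching is one-to-one and in order", {
  obs2 <- topology_model("p", "in", rbind(c(10, 30), c(35, 55)), 80)
  spanning <- topology_model("p", "in", cbind(12, 50), 80)
  expect_equal(match_regions(spanning, obs2), 1L)
  expect_equal(match_regions(obs2, obs2), 2L)
  none <- topology_model("p", "in", matrix(integer(0), 0, 2), 80)
  expect_equal(match_regions(none, obs2), 0L)
  # never more matches than either side has segments
  set.seed(8)
  for (rep in 1:25) {
    a <- random_topology(); b <- random_topology()
    n <- max(a$length, b$length)
    a$length <- b$length <- n
    m <- match_regions(a, b)
    expect_lte(m, min(nrow(a$segments), nrow(b$segments)))
  }
})

test_that("region scores derive M, C and geometric-mean Q from counts", {
  top <- region_score_from_counts(515, 507, 500)
  expect_equal(round_half_up(100 * top$m_frac), 97.09)
  expect_equal(round_half_up(100 * top$c_frac), 98.62)
  expect_equal(round_half_up(100 * top$q), 97.85)
  prodiv <- region_score_from_counts(515, 524, 503)
  expect_equal(round_half_up(100 * prodiv$m_frac), 97.67)
  expect_equal(round_half_up(100 * prodiv$c_frac), 95.99)
  expect_equal(round_half_up(100 * prodiv$q), 96.83)

  perfect <- region_score_from_counts(20, 20, 20)
  expect_equal(c(perfect$m_frac, perfect$c_frac, perfect$q), rep(1, 3))
  expect_error(region_score_from_counts(10, 10, 11), "cannot exceed")
  # geometric mean lies between M and C
  set.seed(4)
  for (rep in 1:20) {
    no <- sample(50:100, 1); np <- sample(50:100, 1)
    nc <- sample(0:min(no, np), 1)
    rs <- region_score_from_counts(no, np, nc)
    expect_gte(rs$q, min(rs$m_frac, rs$c_frac) - 1e-12)
    expect_lte(rs$q, max(rs$m_frac, rs$c_frac) + 1e-12)
  }
})

test_that("topology accuracy counts fully correct proteins", {
  a <- topology_model("p1", "in", cbind(4, 13), 40)
  b <- topology_model("p2", "in", cbind(4, 13), 40)
  b_flip <- topology_model("p2", "out", cbind(4, 13), 40)
  pairs <- list(list(predicted = a, observed = a),
                list(predicted = b_flip, observed = b))
  expect_equal(topology_accuracy(pairs), 0.5)
  expect_equal(topology_accuracy(list(list(predicted = a, observed = a))), 1)
})

test_that("region scoring over pairs sums protein contributions", {
  obs <- list(
    topology_model("p1", "in", rbind(c(10, 30), c(40, 60)), 80),
    topology_model("p2", "out", cbind(5, 25), 40))
  prd <- list(
    topology_model("p1", "in", rbind(c(12, 32), c(42, 58)), 80),
    topology_model("p2", "out", rbind(c(6, 24), c(30, 39)), 40))
  pairs <- Map(function(p, o) list(predicted = p, observed = o), prd, obs)
  rs <- region_scores(pairs)
  expect_equal(rs$n_obs, 3L)
  expect_equal(rs$n_prd, 4L)
  expect_equal(rs$n_cor, 3L)
  expect_equal(rs$q, sqrt((3 / 3) * (3 / 4)), tolerance = 1e-12)
})

test_that("cross-validation is seeded, balanced, and train/test separated", {
  spec <- sim_spec(n_proteins = 25, seed = 55)
  bundle <- simulate_dataset(spec)
  cv1 <- crossvalidate(bundle$observed, bundle$predictor_tracks,
                       n_folds = 5, seed = 9)
  cv2 <- crossvalidate(bundle$observed, bundle$predictor_tracks,
                       n_folds = 5, seed = 9)
  expect_equal(cv1$fold_sizes, rep(5L, 5))
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(unclass(cv1$ensemble$confusion),
               unclass(cv2$ensemble$confusion))
  cv3 <- crossvalidate(bundle$observed, bundle$predictor_tracks,
                       n_folds = 5, seed = 10)
  expect_false(identical(cv1$folds, cv3$folds))

  # pooled individual-predictor accuracy recovers the generating 0.78
  n <- sum(nchar(bundle$sequences))
  se <- sqrt(0.78 * 0.22 / n)
  for (pid in names(cv1$predictors)) {
    expect_lt(abs(cv1$predictors[[pid]]$metrics$accuracy - 0.78), 3 * se)
  }
  expect_error(crossvalidate(bundle$observed[1:3], bundle$predictor_tracks,
                             n_folds = 5), "fewer proteins")
})
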