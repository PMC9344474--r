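test_that("block overlay reproduces the cloud and rescales weights", {
  tl <- tiny_library()
  b <- tl$library$blocks[[1]]
  target <- tl$template
  target$ntc <- b$ntc
  w <- overlay_block(b, target)
  # the library reference IS the template step: cloud reproduced in place
  expect_equal(w$x, b$waters$x, tolerance = 1e-9)
  expect_equal(unique(w$weight), 1 / b$n_steps)

  set.seed(61)
  rot <- random_rot(); trans <- rnorm(3, sd = 10)
  moved <- target
  for (f in c("first", "second")) {
    moved[[f]]$atoms[, c("x", "y", "z")] <-
      rigid(as.matrix(moved[[f]]$atoms[, c("x", "y", "z")]), rot, trans)
  }
  wm <- overlay_block(b, moved)
  expect_equal(as.matrix(wm[, c("x", "y", "z")]),
               rigid(as.matrix(w[, c("x", "y", "z")]), rot, trans),
               tolerance = 1e-6, ignore_attr = TRUE)

  wrong <- make_ideal_step("GC")
  wrong$ntc <- b$ntc
  expect_error(overlay_block(b, wrong), "does not match")
})

make_target_model <- function(tl, seed = 77, with_truth_waters = TRUE) {
  set.seed(seed)
  rot <- random_rot(); trans <- rnorm(3, sd = 12)
  template <- tl$template
  atoms <- rbind(template$first$atoms, template$second$atoms)
  xyz <- rigid(as.matrix(atoms[, c("x", "y", "z")]), rot, trans)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  truth <- as.matrix(tl$spec$planted_sites[, c("x", "y", "z")])
  truth <- rigid(truth, rot, trans)
  if (with_truth_waters) {
    wt <- dnahydro:::new_atom_table(
      atom_name = rep("O", nrow(truth)), element = rep("O", nrow(truth)),
      residue_name = rep("HOH", nrow(truth)), chain_id = rep("W", nrow(truth)),
      residue_number = seq_len(nrow(truth)), ins = rep("", nrow(truth)),
      x = truth[, 1], y = truth[, 2], z = truth[, 3],
      occupancy = rep(1, nrow(truth)), b_factor = rep(0, nrow(truth)),
      altloc = rep("", nrow(truth)))
    atoms <- rbind(atoms, wt)
  }
  model <- structure(
    list(structure_id = "target", resolution = 1.0, model_number = 1L,
         atoms = atoms, cell = NULL, spacegroup = NULL, symops = NULL),
    class = "dnahydro_model")
  list(model = model, truth = truth,
       truth_occ = tl$spec$planted_sites$occupancy,
       truth_cat = tl$spec$planted_sites$category)
}

test_that("prediction on a held-out rigid copy recovers the planted sites", {
  tl <- tiny_library()
  tg <- make_target_model(tl)
  cls <- template_centroid_classifier()
  pred <- predict_hydration(tg$model, tl$library, cls)
  sites <- predicted_sites(pred)
  expect_equal(nrow(sites), 4)
  expect_equal(sum(sites$category == "base"), 2)
  # empirical per-site frequency in the corpus (block frame): the predictor
  # can only recover what was actually drawn, so compare against that
  b0 <- tl$library$blocks[[1]]
  planted <- as.matrix(tl$spec$planted_sites[, c("x", "y", "z")])
  emp <- vapply(seq_len(nrow(planted)), function(i) {
    d <- sqrt((b0$waters$x - planted[i, 1])^2 + (b0$waters$y - planted[i, 2])^2 +
                (b0$waters$z - planted[i, 3])^2)
    sum(d <= 1) / b0$n_steps
  }, numeric(1))
  for (i in seq_len(nrow(tg$truth))) {
    d <- sqrt((sites$x - tg$truth[i, 1])^2 + (sites$y - tg$truth[i, 2])^2 +
                (sites$z - tg$truth[i, 3])^2)
    j <- which.min(d)
    expect_lt(d[j], 0.35)
    expect_lt(abs(sites$occupancy[j] - emp[i]), 0.03)
    expect_lt(abs(emp[i] - tg$truth_occ[i]), 0.15)
    expect_equal(sites$category[j], tg$truth_cat[i])
  }
  # weight conservation: total transferred weight = sum n_waters/n_steps
  b <- tl$library$blocks[[1]]
  expect_equal(pred$total_weight, b$n_waters / b$n_steps, tolerance = 1e-12)
  expect_equal(pred$n_steps_used, 1)
})

test_that("rigid-motion equivariance of whole-structure prediction", {
  tl <- tiny_library()
  tg1 <- make_target_model(tl, seed = 78)
  tg2 <- make_target_model(tl, seed = 79)
  cls <- template_centroid_classifier()
  s1 <- predicted_sites(predict_hydration(tg1$model, tl$library, cls))
  s2 <- predicted_sites(predict_hydration(tg2$model, tl$library, cls))
  # map sites through the truth correspondence: distances to the planted
  # sites are preserved between the two rigid placements
  d1 <- sort(as.numeric(dnahydro:::min_dist_to_set(
    as.matrix(s1[, c("x", "y", "z")]), tg1$truth)))
  d2 <- sort(as.numeric(dnahydro:::min_dist_to_set(
    as.matrix(s2[, c("x", "y", "z")]), tg2$truth)))
  expect_equal(d1, d2, tolerance = density_params()$spacing)
})

test_that("NANT and unknown combinations are skipped with a log", {
  tl <- tiny_library()
  tg <- make_target_model(tl)
  # a classifier whose only centroid is far away: everything becomes NANT
  far <- template_centroid_classifier()
  for (nm in dnahydro:::TORSION_NAMES) far[[nm]] <- (far[[nm]] + 120) %% 360
  pred <- predict_hydration(tg$model, tl$library, far)
  expect_equal(nrow(predicted_sites(pred)), 0)
  expect_true(all(grepl("NANT", pred$per_step_log$status)))

  # unreliable blocks are skipped unless allowed
  strict <- tl$library
  strict$blocks[[1]]$reliable <- FALSE
  pred2 <- predict_hydration(tg$model, strict, template_centroid_classifier())
  expect_equal(nrow(predicted_sites(pred2)), 0)
  expect_true(any(grepl("reliability", pred2$per_step_log$status)))
  pred3 <- predict_hydration(tg$model, strict, template_centroid_classifier(),
                             allow_unreliable = TRUE)
  expect_equal(nrow(predicted_sites(pred3)), 4)

  expect_error(predict_hydration(tg$model,
                                 structure(list(blocks = list()),
                                           class = "dnahydro_library"),
                                 template_centroid_classifier()),
               "empty block library")
})

test_that("evaluation bins distances at 0.5 A and counts conserve", {
  tl <- tiny_library()
  tg <- make_target_model(tl)
  cls <- template_centroid_classifier()
  pred <- predict_hydration(tg$model, tl$library, cls)
  obs <- extract_waters(tg$model)
  ev <- evaluate_prediction(pred, obs)
  expect_equal(sum(ev$histogram$overall), nrow(predicted_sites(pred)))
  expect_equal(ev$histogram$base + ev$histogram$backbone, ev$histogram$overall)
  expect_equal(unname(ev$frac_within_1A["overall"]), 1.0)
  # frac equals the first two bins over the total
  expect_equal(unname(ev$frac_within_1A["overall"]),
               sum(ev$histogram$overall[1:2]) / sum(ev$histogram$overall))
  expect_error(evaluate_prediction(pred, obs[0, ]), "meaningless")
})

test_that("evaluation takes the nearest water including symmetry mates", {
  tl <- tiny_library()
  tg <- make_target_model(tl, with_truth_waters = FALSE)
  cls <- template_centroid_classifier()
  pred <- predict_hydration(tg$model, tl$library, cls)
  sites <- predicted_sites(pred)
  s1 <- as.numeric(sites[1, c("x", "y", "z")])
  # an ASU water 2.0 A away and a "mate" 0.8 A away
  obs <- data.frame(x = c(s1[1] + 2.0, s1[1] + 0.8), y = s1[2], z = s1[3],
                    water_id = c("a", "a"), op_index = c(0L, 2L))
  ev <- evaluate_prediction(pred, obs)
  expect_equal(ev$distances$distance[1], 0.8, tolerance = 1e-9)
  # order of the site table does not change the histogram
  pred_rev <- pred
  pred_rev$base_sites <- pred$base_sites[rev(seq_len(nrow(pred$base_sites))), ]
  ev2 <- evaluate_prediction(pred_rev, obs)
  expect_equal(ev2$histogram$overall, ev$histogram$overall)
})
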