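water_df <- function(xyz, id = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             water_id = id %||% paste0("w", seq_len(nrow(xyz))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("water association applies the 4.0 A cutoff and dual flags", {
  step <- make_ideal_step("CG")
  at <- step_atoms(step)
  axyz_all <- as.matrix(at[, c("x", "y", "z")])
  centroid <- colMeans(at[, c("x", "y", "z")])
  anchor <- as.numeric(at[at$label == "2:N7", c("x", "y", "z")])
  dirv <- (anchor - centroid) / sqrt(sum((anchor - centroid)^2))
  # solve for points whose minimum distance to the step is 3.9 / 4.1 A
  mind <- function(t) {
    min(dnahydro:::min_dist_to_set(rbind(anchor + t * dirv), axyz_all))
  }
  t_near <- uniroot(function(t) mind(t) - 3.9, c(0.1, 20))$root
  t_far <- uniroot(function(t) mind(t) - 4.1, c(0.1, 20))$root
  near <- anchor + t_near * dirv
  far <- anchor + t_far * dirv
  aw <- associate_waters(step, water_df(rbind(near, far)))
  expect_equal(nrow(aw), 1)
  expect_equal(aw$water_id, "w1")
  expect_lt(aw$nearest_distance, 4.0)

  # a water between categories carries both flags: search midpoints of
  # nearby base/backbone atom pairs for a position within 3.4 A of both sets
  base_xyz <- as.matrix(at[at$is_base, c("x", "y", "z")])
  bb_xyz <- as.matrix(at[!at$is_base, c("x", "y", "z")])
  found <- NULL
  for (ib in seq_len(nrow(base_xyz))) {
    for (ik in seq_len(nrow(bb_xyz))) {
      cand <- (base_xyz[ib, ] + bb_xyz[ik, ]) / 2
      db <- min(dnahydro:::min_dist_to_set(rbind(cand), base_xyz))
      dk <- min(dnahydro:::min_dist_to_set(rbind(cand), bb_xyz))
      if (db < 3.4 && dk < 3.4 && db > 1.5 && dk > 1.5) { found <- cand; break }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  aw2 <- associate_waters(step, water_df(found))
  expect_true(aw2$near_base && aw2$near_backbone)

  # association is invariant to water input order
  set.seed(44)
  pts <- sweep(matrix(rnorm(60, 0, 4), 20, 3), 2, centroid, "+")
  a1 <- associate_waters(step, water_df(pts))
  a2 <- associate_waters(step, water_df(pts[20:1, ],
                                        id = paste0("w", 20:1)))
  expect_setequal(a1$water_id, a2$water_id)
})

test_that("water transfer is exact for identity and composed transforms", {
  ref <- make_ideal_step("CG")
  w <- as.numeric(step_atoms(ref)[5, c("x", "y", "z")]) + c(2.5, 0.3, -0.7)
  tr0 <- transfer_water(w, ref, ref)
  expect_equal(tr0$position, w, tolerance = 1e-9)
  expect_equal(tr0$rmsd, 0, tolerance = 1e-9)

  set.seed(17)
  rot <- random_rot(); trans <- rnorm(3, sd = 8)
  moved <- ref
  for (f in c("first", "second")) {
    moved[[f]]$atoms[, c("x", "y", "z")] <-
      rigid(as.matrix(moved[[f]]$atoms[, c("x", "y", "z")]), rot, trans)
  }
  w_moved <- as.numeric(rigid(rbind(w), rot, trans))
  tr <- transfer_water(w_moved, moved, ref)
  expect_equal(tr$position, w, tolerance = 1e-6)
  expect_equal(tr$rmsd, 0, tolerance = 1e-6)
})

test_that("the six alignment atoms match a brute-force distance sort", {
  step <- make_ideal_step("GT")
  at <- step_atoms(step)
  # water nearer residue 2
  anchor <- as.numeric(at[at$label == "2:N3", c("x", "y", "z")])
  centroid <- colMeans(at[, c("x", "y", "z")])
  w <- anchor + 2.6 * (anchor - centroid) / sqrt(sum((anchor - centroid)^2))
  sel <- dnahydro:::six_nearest_shared(w, at, at$label)
  d <- sqrt((at$x - w[1])^2 + (at$y - w[2])^2 + (at$z - w[3])^2)
  brute <- at$label[order(d, at$res_index, at$atom_name)][1:6]
  expect_setequal(sel$label, brute)
  expect_true(all(sel$res_index == 2))
})

test_that("transfer equivariance holds across random rigid transforms", {
  ref <- make_ideal_step("CG")
  at <- step_atoms(ref)
  centroid <- colMeans(at[, c("x", "y", "z")])
  set.seed(23)
  waters <- sweep(matrix(rnorm(30, 0, 3), 10, 3), 2, centroid, "+")
  for (rep in 1:10) {
    rot <- random_rot(); trans <- rnorm(3, sd = 15)
    moved <- ref
    for (f in c("first", "second")) {
      moved[[f]]$atoms[, c("x", "y", "z")] <-
        rigid(as.matrix(moved[[f]]$atoms[, c("x", "y", "z")]), rot, trans)
    }
    for (i in seq_len(nrow(waters))) {
      w <- as.numeric(waters[i, ])
      tr_direct <- transfer_water(w, ref, ref)
      tr_moved <- transfer_water(as.numeric(rigid(rbind(w), rot, trans)),
                                 moved, ref)
      expect_equal(tr_moved$position, tr_direct$position, tolerance = 1e-6)
    }
  }
})

test_that("block assembly counts waters and applies the reliability boundary", {
  ap <- assoc_params(min_waters_reliable = 6)
  ref <- make_ideal_step("CG")
  at <- step_atoms(ref)
  centroid <- colMeans(at[, c("x", "y", "z")])
  anchor <- as.numeric(at[at$label == "2:N7", c("x", "y", "z")])
  w2 <- rbind(anchor + c(1.8, 0, 0), anchor + c(0, 1.8, 0))
  hs <- lapply(1:3, function(i) {
    list(step = ref, waters = associate_waters(ref, water_df(w2), ap))
  })
  b <- build_block("BB00", "CG", hs, reference = ref, params = ap)
  expect_equal(b$n_steps, 3)
  expect_equal(b$n_waters, 6)
  expect_true(b$reliable)           # exactly at the >= boundary
  expect_equal(b$n_waters, b$n_associated)

  b5 <- build_block("BB00", "CG", hs[1:2], reference = ref,
                    params = assoc_params(min_waters_reliable = 5))
  expect_equal(b5$n_waters, 4)
  expect_false(b5$reliable)

  empty <- build_block("BB00", "CG", list(), params = ap)
  expect_equal(empty$n_waters, 0)
  expect_false(empty$reliable)

  other <- make_ideal_step("GC")
  expect_error(
    build_block("BB00", "CG",
                list(list(step = other, waters = water_df(centroid)[0, ]))),
    "mixed")
})

test_that("blocks conserve association counts for rigid corpora", {
  tl <- tiny_library()
  b <- tl$library$blocks[[1]]
  n_assoc <- sum(vapply(tl$corpus$models, function(m) {
    res <- residues_from_model(m, "A")
    step <- extract_steps(res)[[1]]
    nrow(associate_waters(step, extract_waters(m), tl$params))
  }, numeric(1)))
  expect_equal(b$n_waters, n_assoc)
  expect_equal(b$n_steps, length(tl$corpus$models))
  # every transferred water stays within the association bound of the
  # reference (rigid transfer: rmsd 0)
  d <- dnahydro:::min_dist_to_set(
    as.matrix(b$waters[, c("x", "y", "z")]),
    as.matrix(b$reference[, c("x", "y", "z")]))
  expect_true(all(d < tl$params$d_assoc + 2 * tl$params$transfer_max_rmsd))
  expect_true(all(b$waters$transfer_rmsd < 1e-6))
})

test_that("a block library round-trips through its on-disk layout", {
  tl <- tiny_library()
  dir <- withr::local_tempdir()
  save_block_library(tl$library, dir)
  back <- load_block_library(dir)
  expect_equal(names(back$blocks), names(tl$library$blocks))
  b0 <- tl$library$blocks[[1]]; b1 <- back$blocks[[1]]
  expect_equal(b1$n_waters, b0$n_waters)
  expect_equal(b1$n_steps, b0$n_steps)
  expect_equal(b1$waters$x, b0$waters$x, tolerance = 1e-9)
  expect_equal(b1$reference$label, b0$reference$label)
  expect_equal(back$params$d_assoc, tl$params$d_assoc)
  expect_error(load_block_library(withr::local_tempdir()), "manifest")
})
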