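test_that("step extraction yields one step per linked pair", {
  m <- make_ideal_model("ACGTAC")
  res <- residues_from_model(m, "A")
  steps <- extract_steps(res)
  expect_length(steps, 5)
  expect_equal(vapply(steps, function(s) s$seq2, character(1)),
               c("AC", "CG", "GT", "TA", "AC"))
  expect_length(extract_steps(res[1:2]), 1)

  # chain break: displace residues 4-6 far away and verify against a
  # brute-force O3'-P linkage scan
  broken <- res
  for (i in 4:6) {
    broken[[i]]$atoms[, c("x", "y", "z")] <-
      broken[[i]]$atoms[, c("x", "y", "z")] + 50
  }
  linked <- vapply(1:5, function(i) {
    o3 <- broken[[i]]$atoms
    o3 <- as.numeric(o3[o3$atom_name == "O3'", c("x", "y", "z")])
    p <- broken[[i + 1]]$atoms
    p <- as.numeric(p[p$atom_name == "P", c("x", "y", "z")])
    sqrt(sum((o3 - p)^2)) <= 2.5
  }, logical(1))
  got <- extract_steps(broken)
  expect_length(got, sum(linked))
  expect_equal(nrow(attr(got, "skipped")), sum(!linked))
})

test_that("atom partition is by name, complete and disjoint", {
  for (s2 in c("AG", "CT", "GC", "TA")) {
    step <- make_ideal_step(s2)
    for (r in list(step$first, step$second)) {
      p <- partition_atoms(r)
      expect_length(intersect(p$base, p$backbone), 0)
      expect_setequal(c(p$base, p$backbone), r$atoms$atom_name)
    }
  }
  g <- make_ideal_step("CG")$second
  p <- partition_atoms(g)
  expect_true("N7" %in% p$base)
  expect_true("OP2" %in% p$backbone)
  expect_true(all(c("C1'", "O4'") %in% p$backbone))
  t_res <- make_ideal_step("GT")$second
  expect_true("C7" %in% partition_atoms(t_res)$base)
})

test_that("dihedrals are analytic for planar arrangements", {
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)),
               180)
  expect_true(is.na(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                   c(3, 1, 0))))
})

test_that("step torsions are rigid-motion invariant and complete", {
  step <- make_ideal_step("CG")
  tv <- step_torsions(step)
  expect_true(attr(tv, "complete"))
  expect_true(all(tv >= 0 & tv < 360))
  set.seed(8)
  rot <- random_rot()
  tr <- rnorm(3, sd = 10)
  moved <- step
  for (f in c("first", "second")) {
    xyz <- rigid(as.matrix(moved[[f]]$atoms[, c("x", "y", "z")]), rot, tr)
    moved[[f]]$atoms$x <- xyz[, 1]
    moved[[f]]$atoms$y <- xyz[, 2]
    moved[[f]]$atoms$z <- xyz[, 3]
  }
  expect_equal(as.numeric(step_torsions(moved)), as.numeric(tv),
               tolerance = 1e-6)
})

test_that("the built-in torsions match the template generator settings", {
  tv <- step_torsions(make_ideal_step("CG", form = "B"))
  geom <- dnahydro:::TEMPLATE_GEOM$B
  expect_equal(unname(tv["delta1"]), unname(geom$tor["de"]), tolerance = 1e-6)
  expect_equal(unname(tv["alpha2"]), unname(geom$tor["al"]), tolerance = 1e-6)
  expect_equal(unname(tv["zeta1"]), unname(geom$tor["ze"]), tolerance = 1e-6)
  expect_equal(unname(tv["chi2"]), unname(geom$chi), tolerance = 1e-6)
})

test_that("nearest-centroid assignment handles exact hits, ties and rejection", {
  tvB <- as.numeric(step_torsions(make_ideal_step("CG", "B")))
  tvA <- as.numeric(step_torsions(make_ideal_step("CG", "A")))
  mk <- function(labels, rows) {
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- dnahydro:::TORSION_NAMES
    classifier_table(cbind(data.frame(label = labels), df))
  }
  tab <- mk(c("BB00", "AA00"), list(tvB, tvA))
  expect_equal(assign_ntc(make_ideal_step("CG", "B"), tab), "BB00")
  expect_equal(assign_ntc(make_ideal_step("CG", "A"), tab), "AA00")

  # rotation invariance of the assignment
  step <- make_ideal_step("CG", "B")
  set.seed(12)
  xyz <- rigid(as.matrix(step$first$atoms[, c("x", "y", "z")]), random_rot(),
               c(3, -7, 2))
  step$first$atoms[, c("x", "y", "z")] <- xyz
  # (rotating only one residue changes inter-residue torsions; rotate both)
  step2 <- make_ideal_step("CG", "B")
  rot <- random_rot(); tr <- rnorm(3, sd = 4)
  for (f in c("first", "second")) {
    step2[[f]]$atoms[, c("x", "y", "z")] <-
      rigid(as.matrix(step2[[f]]$atoms[, c("x", "y", "z")]), rot, tr)
  }
  expect_equal(assign_ntc(step2, tab), "BB00")

  # tie between two equidistant centroids resolves by vocabulary order
  shift1 <- tvB; shift1[1] <- (shift1[1] + 10) %% 360
  shift2 <- tvB; shift2[1] <- (shift2[1] - 10) %% 360
  tie_tab <- mk(c("BB07", "AB01"), list(shift1, shift2))
  expect_equal(assign_ntc(make_ideal_step("CG", "B"), tie_tab), "AB01")
  expect_lt(match("AB01", ntc_classes()), match("BB07", ntc_classes()))

  # all centroids beyond the rejection radius: NANT
  far <- (tvB + 120) %% 360
  expect_equal(assign_ntc(make_ideal_step("CG", "B"), mk("BB00", list(far))),
               "NANT")
})

test_that("lookup assignment returns tabulated labels and NANT otherwise", {
  tab <- classifier_table(data.frame(
    structure_id = "s1", chain_id = "A", residue_number = 1L, label = "BB07"))
  step <- make_ideal_step("CG")
  step$source <- list(structure_id = "s1", chain_id = "A", residue_number = 1L)
  expect_equal(assign_ntc(step, tab), "BB07")
  step$source$residue_number <- 2L
  expect_equal(assign_ntc(step, tab), "NANT")
})

test_that("classifier tables validate labels and round-trip as TSV", {
  expect_error(classifier_table(data.frame(
    structure_id = "s", chain_id = "A", residue_number = 1L, label = "XX99")),
    "vocabulary")
  expect_error(classifier_table(data.frame(a = 1)), "centroid or an assignment")
  tab <- template_centroid_classifier()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_classifier_table(tab, f)
  back <- read_classifier_table(f)
  expect_equal(attr(back, "dialect"), "centroid")
  expect_equal(back$delta1, tab$delta1, tolerance = 1e-9)
})

test_that("reference selection minimizes superposed rmsd, brute-force checked", {
  set.seed(31)
  template <- make_ideal_step("CG")
  noisy_copy <- function(sigma) {
    s <- template
    for (f in c("first", "second")) {
      n <- nrow(s[[f]]$atoms)
      s[[f]]$atoms[, c("x", "y", "z")] <- s[[f]]$atoms[, c("x", "y", "z")] +
        matrix(rnorm(3 * n, 0, sigma), n, 3)
    }
    s
  }
  cands <- list(noisy_copy(0.3), noisy_copy(0.1), noisy_copy(0.5))
  ref_tab <- step_atoms(template)
  chosen <- select_reference(cands, representative = ref_tab)
  rms <- vapply(cands, function(s) {
    a <- step_atoms(s)
    superposed_rmsd(as.matrix(a[, c("x", "y", "z")]),
                    as.matrix(ref_tab[match(a$label, ref_tab$label),
                                      c("x", "y", "z")]))
  }, numeric(1))
  expect_equal(chosen, cands[[which.min(rms)]])
  expect_equal(which.min(rms), 2)   # the sigma = 0.1 copy
  # exact copy wins outright; singleton returns itself
  expect_equal(select_reference(c(cands, list(template)),
                                representative = ref_tab), template)
  expect_equal(select_reference(cands[2]), cands[[2]])
  expect_error(select_reference(list()), "empty")
})

test_that("conformer/sequence bookkeeping conserves step counts", {
  m <- make_ideal_model("ACGTACGTAC")
  res <- residues_from_model(m, "A")
  steps <- extract_steps(res)
  labs <- vapply(seq_along(steps), function(i) {
    c("BB00", "BB07")[i %% 2 + 1]
  }, character(1))
  seqs <- vapply(steps, function(s) s$seq2, character(1))
  tab <- table(labs, seqs)
  expect_equal(sum(tab), length(steps))
  expect_lte(length(unique(seqs)), 16)
  expect_true(all(labs %in% ntc_classes()))
})
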