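test_that("waters per nucleotide applies the strict 3.4 A contact rule", {
  m <- make_ideal_model("ACGTAC", structure_id = "wpn")
  at <- m$atoms
  add_water <- function(m, xyz) {
    w <- dnahydro:::new_atom_table(
      atom_name = "O", element = "O", residue_name = "HOH", chain_id = "W",
      residue_number = sum(m$atoms$is_water) + 1L, ins = "",
      x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1, b_factor = 0,
      altloc = "")
    m$atoms <- rbind(m$atoms, w)
    m
  }
  p1 <- as.numeric(at[1, c("x", "y", "z")])
  # one water at an atom position (distance 0): counted
  m1 <- add_water(m, p1)
  expect_equal(waters_per_nucleotide(m1, "A"), 1 / 6)
  # a water at exactly 3.5 A from its nearest atom: not counted
  far <- m
  dirs <- p1 - colMeans(as.matrix(at[, c("x", "y", "z")]))
  dirs <- dirs / sqrt(sum(dirs^2))
  axyz <- as.matrix(at[!at$is_water, c("x", "y", "z")])
  t35 <- uniroot(function(t) {
    min(dnahydro:::min_dist_to_set(rbind(p1 + t * dirs), axyz)) - 3.5
  }, c(0.1, 30))$root
  far <- add_water(far, p1 + t35 * dirs)
  wd <- extract_waters(far)
  dmin <- min(dnahydro:::min_dist_to_set(
    as.matrix(wd[, c("x", "y", "z")]),
    as.matrix(at[!at$is_water, c("x", "y", "z")])))
  expect_gte(dmin, 3.4)
  expect_equal(waters_per_nucleotide(far, "A"), 0)
  # 12-nt chain with 15 qualifying waters gives 1.25
  m12 <- make_ideal_model(strrep("AC", 6), structure_id = "wpn12")
  for (i in 1:15) {
    anchor <- as.numeric(m12$atoms[i * 7, c("x", "y", "z")])
    m12 <- add_water(m12, anchor + c(1.5, 0, 0) * 0 + c(0, 0, 2.0))
  }
  w12 <- extract_waters(m12)
  d12 <- dnahydro:::min_dist_to_set(
    as.matrix(w12[, c("x", "y", "z")]),
    as.matrix(m12$atoms[!m12$atoms$is_water, c("x", "y", "z")]))
  expect_true(all(d12 < 3.4))
  expect_equal(waters_per_nucleotide(m12, "A"), 15 / 12)
})

test_that("sequence clustering matches the brute-force closure oracle", {
  params <- curation_params()
  # equal-length rules
  e <- chain_table(c("s1", "s2", "s3"), c("A", "A", "A"), c(1.5, 1.6, 1.7),
                   c("ACGTACGTACGT", "ACGTACGTACAA", "ACGTACGTAAAA"),
                   c(2, 2, 2))
  cl <- cluster_chains(e, params)
  # s1-s2 differ at 2 (join); s2-s3 differ at 2 (join); closure puts all 3
  expect_equal(length(unique(cl$cluster_id)), 1)
  e2 <- chain_table(c("s1", "s2"), c("A", "A"), c(1.5, 1.6),
                    c("ACGTACGTACGT", "ACGTACGTAAAA"), c(2, 2))
  expect_equal(length(unique(cluster_chains(e2, params)$cluster_id)), 2)

  set.seed(99)
  for (rep in 1:5) {
    n <- 12
    lens <- sample(c(8, 10, 12, 26), n, replace = TRUE)
    seqs <- vapply(lens, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
    # seed a few near-duplicates to make clustering non-trivial
    seqs[2] <- seqs[1]
    sub <- strsplit(seqs[3], "")[[1]]
    sub[1:2] <- c("A", "A")
    seqs[4] <- paste(sub, collapse = "")
    ent <- chain_table(sprintf("s%02d", 1:n), rep("A", n),
                      runif(n, 1, 2), seqs, runif(n, 1, 3))
    ours <- cluster_chains(ent, params)$cluster_id
    orc <- brute_force_clusters(ent, params)
    # same partitions (labels may differ)
    expect_equal(length(unique(ours)), length(unique(orc)))
    expect_true(all(tapply(orc, ours, function(v) length(unique(v))) == 1))
  }
})

test_that("representatives follow resolution, the 0.1 A tie window, waters", {
  params <- curation_params()
  cl <- chain_table(c("a", "b"), c("A", "A"), c(1.5, 1.9),
                    c("ACGTACGT", "ACGTACGT"), c(2.0, 3.0))
  expect_equal(select_representative(cl, params)$structure_id, "a")
  cl2 <- chain_table(c("a", "b"), c("A", "A"), c(1.50, 1.55),
                     c("ACGTACGT", "ACGTACGT"), c(1.2, 2.0))
  expect_equal(select_representative(cl2, params)$structure_id, "b")
  single <- chain_table("z", "B", 2.0, "ACGTACGT", 1.1)
  expect_equal(select_representative(single, params)$structure_id, "z")
  # invariance to member ordering
  cl3 <- chain_table(c("c", "a", "b"), c("A", "A", "A"), c(1.58, 1.50, 1.55),
                     c("ACGTACGT", "ACGTACGT", "ACGTACGT"), c(9.0, 1.2, 2.0))
  expect_equal(select_representative(cl3, params)$structure_id,
               select_representative(cl3[c(2, 3, 1), ], params)$structure_id)
  expect_error(select_representative(cl3[0, ], params), "empty")
})

test_that("the chain filters use inclusive 2.6 A and exclusive 1.0 w/nt", {
  params <- curation_params()
  e <- chain_table(c("k1", "k2", "k3", "k4"), rep("A", 4),
                   c(2.6, 2.7, 1.0, 1.2),
                   rep("ACGTAC", 4), c(1.2, 5.0, 1.0, 2.0))
  out <- filter_chains(e, params)
  expect_equal(out$structure_id, c("k1", "k4"))
  # short chains are dropped at intake
  e5 <- chain_table("k5", "A", 1.0, "ACGTA", 3.0)
  expect_equal(nrow(filter_chains(e5, params)), 0)
})

test_that("filter -> cluster -> select on a 10-entry table is reproduced exactly", {
  e <- chain_table(
    structure_id = sprintf("t%02d", 1:10),
    chain_id = rep("A", 10),
    resolution = c(1.50, 1.55, 1.90, 2.60, 2.70, 1.20, 1.20, 2.00, 1.00, 1.80),
    sequence = c("ACGTACGTACGT",  # t01 cluster I
                 "ACGTACGTACAA",  # t02 cluster I (2 mismatches from t01)
                 "ACGTACGTACGT",  # t03 cluster I
                 "GGGGCCCCGGGG",  # t04 cluster II
                 "GGGGCCCCGGGG",  # t05 dropped: resolution 2.7
                 "TTTTAAAATTTT",  # t06 cluster III
                 "TTTTAAAATTTT",  # t07 cluster III (tie with t06)
                 "TTTTAAAATTAA",  # t08 cluster III (2 mismatches)
                 "CCCCCCCCCCCC",  # t09 dropped: waters 1.0 (not > 1.0)
                 "ACAC"),         # t10 dropped: shorter than 6 nt
    waters_per_nucleotide = c(2.0, 3.5, 9.9, 1.2, 9.9, 2.0, 2.0, 9.9, 1.0, 9.9))
  # hand-computed expectation:
  #  cluster I  = {t01, t02, t03}: best res 1.50 (t01), window [<=1.60] adds
  #               t02 (1.55, wpn 3.5 > 2.0) -> t02 wins
  #  cluster II = {t04}: t04 (2.60 kept, inclusive boundary)
  #  cluster III= {t06, t07, t08}: t06/t07 at 1.20 tie on wpn 2.0 ->
  #               lexicographic t06; t08 (2.00) outside window
  reps <- curate_chains(e, curation_params())
  expect_equal(sort(reps$structure_id), c("t02", "t04", "t06"))
  att <- attr(reps, "attrition")
  expect_equal(unname(att["input"]), 10)
  expect_equal(unname(att["filtered"]), 7)
  expect_equal(unname(att["clusters"]), 3)
})

test_that("chain tables round-trip through CSV", {
  e <- chain_table(c("x1", "x2"), c("A", "B"), c(1.2, 2.0),
                   c("ACGTAC", "GGGCCC"), c(1.5, 2.5), c(TRUE, FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_chain_table(e, f)
  back <- read_chain_table(f)
  expect_equal(back$structure_id, e$structure_id)
  expect_equal(back$waters_per_nucleotide, e$waters_per_nucleotide)
  expect_equal(back$is_complexed, e$is_complexed)
  expect_equal(back$n_nuc, c(6, 6))
})
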