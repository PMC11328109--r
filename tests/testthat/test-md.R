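# Build a single frame from the toy protein plus explicitly placed SCN ions.
# `positions` is a list of 3x3 coordinate matrices (rows N, C, S).
frame_with_scn <- function(positions) {
  prot <- toy_protein()
  rows <- prot$atoms
  xyz <- prot$xyz
  eleno <- max(rows$eleno)
  for (i in seq_along(positions)) {
    rows <- rbind(rows, data.frame(
      eleno = eleno + 3 * (i - 1) + 1:3, elety = c("N", "C", "S"),
      resid = "SCN", chain = "B", resno = 100 + i,
      elesy = c("N", "C", "S")))
    xyz <- c(xyz, as.numeric(t(positions[[i]])))
  }
  trajectory_frames(rows, matrix(xyz, nrow = 1))
}

# Outward unit vector through a named atom of a residue.
outward <- function(prot, resid, elety) {
  co <- matrix(prot$xyz, ncol = 3, byrow = TRUE)
  heavy <- co[!(substr(prot$atoms$elety, 1, 1) == "H"), , drop = FALSE]
  ctr <- colMeans(heavy)
  at <- co[which(prot$atoms$resid == resid & prot$atoms$elety == elety), ]
  list(at = at, dir = (at - ctr) / sqrt(sum((at - ctr)^2)))
}

scn_along <- function(anchor, dir, dist) {
  rbind(anchor + dist * dir,
        anchor + (dist + 1.17) * dir,
        anchor + (dist + 2.81) * dir)
}

test_that("shell counting matches construction and the exhaustive oracle", {
  fr <- make_frame_set(list(c(3.5, 3.9, 4.5)), seed = 1)
  expect_equal(ions_in_shell(fr, cutoff = 4.0), 2L)
  expect_equal(ions_in_shell(fr, cutoff = 3.0), 0L)
  no_ions <- {
    prot <- toy_protein()
    trajectory_frames(prot$atoms, matrix(prot$xyz, nrow = 1))
  }
  expect_equal(ions_in_shell(no_ions, 4.0), 0L)
  # oracle equivalence on randomized frame sets
  set.seed(42)
  plans <- replicate(12, runif(8, 2.5, 9), simplify = FALSE)
  fr2 <- make_frame_set(plans, seed = 5)
  for (i in seq_len(fr2$n_frames)) {
    d_oracle <- oracle_ion_min_dists(fr2, i)
    expect_equal(sum(d_oracle <= 4.0), ions_in_shell(fr2, 4.0)[i])
    expect_equal(sort(unname(d_oracle)), sort(plans[[i]]), tolerance = 1e-6)
  }
  # monotone in cutoff
  for (cut in c(3, 4, 5, 7)) {
    expect_true(all(ions_in_shell(fr2, cut) <= ions_in_shell(fr2, cut + 1)))
  }
})

test_that("occupancy histograms and means follow the per-frame counts", {
  fr <- make_frame_set(list(c(3, 3.5), c(3, 3.6), c(3.2, 3.4), c(5, 4.5)),
                       seed = 2)
  occ <- occupancy_series(fr, 4.0)
  expect_equal(occ$counts, c(2L, 2L, 2L, 0L))
  expect_equal(occ$mean, 1.5)
  expect_equal(sum(occ$histogram$percent), 100, tolerance = 1e-9)
  expect_equal(occ$histogram$percent[occ$histogram$count == 2], 75)
  # weighted-mean additivity across concatenated frame sets
  f1 <- make_frame_set(list(c(3, 3), c(3, 5)), seed = 3)
  f2 <- make_frame_set(list(c(5, 5), c(3, 3), c(3, 3)), seed = 4)
  m12 <- (2 * occupancy_series(f1)$mean +
            3 * occupancy_series(f2)$mean) / 5
  joint <- trajectory_frames(f1$atoms, rbind(f1$xyz, f2$xyz))
  expect_equal(occupancy_series(joint)$mean, m12)
  # single frame: all mass on one count
  single <- make_frame_set(list(c(3, 3.1, 3.2)), seed = 6)
  h <- occupancy_series(single)$histogram
  expect_equal(h$percent[h$count == 3], 100)
})

test_that("side-chain contacts classify, deduplicate and match the
           oracle", {
  prot <- toy_protein()
  # one SCN 3.0 A beyond the lysine NZ, pointing away from everything else
  o <- outward(prot, "LYS", "NZ")
  fr <- frame_with_scn(list(scn_along(o$at, o$dir, 3.0)))
  cc <- side_chain_contacts(fr, 1, cutoff = 4.0)
  expect_equal(unname(cc["positive"]), 1L)
  expect_equal(unname(cc[c("negative", "aromatic", "aliphatic")]),
               c(0L, 0L, 0L))
  # ion within reach of two atoms of the same leucine: one contact pair
  co <- matrix(prot$xyz, ncol = 3, byrow = TRUE)
  cd1 <- co[which(prot$atoms$resid == "LEU" & prot$atoms$elety == "CD1"), ]
  cd2 <- co[which(prot$atoms$resid == "LEU" & prot$atoms$elety == "CD2"), ]
  mid <- (cd1 + cd2) / 2
  dir <- mid / sqrt(sum(mid^2))
  fr2 <- frame_with_scn(list(scn_along(mid, dir, 2.0)))
  pair <- side_chain_contacts(fr2, 1, cutoff = 4.0)
  expect_equal(unname(pair["aliphatic"]), 1L)
  atomwise <- side_chain_contacts(fr2, 1, cutoff = 4.0, per_atom = TRUE)
  expect_gt(unname(atomwise["aliphatic"]), 1L)
  # oracle equivalence, both counting conventions
  fr3 <- make_frame_set(replicate(6, runif(6, 2.5, 7), simplify = FALSE),
                        seed = 11)
  for (i in seq_len(fr3$n_frames)) {
    expect_equal(side_chain_contacts(fr3, i),
                 oracle_contacts(fr3, i))
    expect_equal(side_chain_contacts(fr3, i, per_atom = TRUE),
                 oracle_contacts(fr3, i, per_atom = TRUE))
  }
})

test_that("contact statistics aggregate per-frame counts", {
  fr <- make_frame_set(list(c(3, 3), c(3, 9), c(9, 9)), seed = 12)
  per_frame <- vapply(1:3, function(i) side_chain_contacts(fr, i),
                      setNames(integer(4),
                               c("positive", "negative", "aromatic",
                                 "aliphatic")))
  st <- contact_stats(fr)
  for (k in seq_len(nrow(st))) {
    expect_equal(st$min[k], min(per_frame[k, ]))
    expect_equal(st$max[k], max(per_frame[k, ]))
    expect_equal(st$mean[k], mean(per_frame[k, ]))
  }
  expect_true(all(st$min <= st$mean & st$mean <= st$max))
})

test_that("minimum-distance distributions bin per-ion minima", {
  prot <- toy_protein()
  o <- outward(prot, "TYR", "OH")
  fr <- frame_with_scn(list(scn_along(o$at, o$dir, 2.9)))
  md <- min_distance_distribution(fr, ion_atom = "N", bin_width = 0.05)
  expect_equal(length(md$distances), 1L)
  expect_equal(md$distances, 2.9, tolerance = 1e-9)
  hit <- md$histogram[md$histogram$count > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$bin_left_A <= md$distances + 1e-9 &&
                md$distances < hit$bin_left_A + 0.05 + 1e-9)
  # sulfur points away: its minimum distance exceeds the nitrogen's
  ms <- min_distance_distribution(fr, ion_atom = "S", bin_width = 0.05)
  expect_gt(ms$distances, md$distances)
  # beyond max_range: empty histogram with warning
  expect_warning(
    far <- min_distance_distribution(fr, "N", max_range = 1.0),
    "max_range")
  expect_equal(nrow(far$histogram), 0L)
  # no thiocyanate at all
  bare <- trajectory_frames(prot$atoms, matrix(prot$xyz, nrow = 1))
  expect_error(min_distance_distribution(bare, "N"), "no ions")
  # oracle equivalence and completeness of the histogram
  fr2 <- make_frame_set(replicate(8, runif(5, 2.5, 8), simplify = FALSE),
                        seed = 13)
  md2 <- min_distance_distribution(fr2, "N", bin_width = 0.1)
  want <- unlist(lapply(seq_len(fr2$n_frames), function(i)
    oracle_ion_min_dists(fr2, i, element = "N")))
  expect_equal(sort(md2$distances), sort(unname(want)), tolerance = 1e-12)
  expect_equal(sum(md2$histogram$count), fr2$n_frames * 5)
})

test_that("multi-model PDB round-trips through read_frames/write_frames", {
  fr <- make_frame_set(list(c(3, 4.5, 6), c(3.3, 4.1, 5.5)), seed = 14)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_frames(fr, path)
  back <- read_frames(path)
  expect_equal(back$n_frames, 2L)
  expect_equal(back$xyz, fr$xyz, tolerance = 1e-3)
  expect_equal(sum(back$atoms$is_ion), sum(fr$atoms$is_ion))
  expect_equal(ions_in_shell(back, 4.0), ions_in_shell(fr, 4.0))
  # a file without MODEL records is a single frame
  p2 <- withr::local_tempfile(fileext = ".pdb")
  first_model <- readLines(path)
  i_end <- which(grepl("^ENDMDL", first_model))[1]
  writeLines(first_model[2:(i_end - 1)], p2)
  one <- read_frames(p2)
  expect_equal(one$n_frames, 1L)
  # malformed coordinate record reported with its line number
  bad <- readLines(p2)
  bad[3] <- substr(bad[3], 1, 40)
  p3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, p3)
  expect_error(read_frames(p3), "line 3")
})

test_that("frame containers validate ion composition and coordinates", {
  prot <- toy_protein()
  rows <- rbind(prot$atoms, data.frame(
    eleno = max(prot$atoms$eleno) + 1:2, elety = c("S", "C"),
    resid = "SCN", chain = "B", resno = 101, elesy = c("S", "C")))
  xyz <- c(prot$xyz, rep(50, 6))
  expect_error(trajectory_frames(rows, matrix(xyz, nrow = 1)),
               "\\{S, C, N\\}")
  xyz_bad <- prot$xyz
  xyz_bad[5] <- NA
  expect_error(trajectory_frames(prot$atoms, matrix(xyz_bad, nrow = 1)),
               "finite")
})
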