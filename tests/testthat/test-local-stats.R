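mk_part <- function(labels, directions = rep(NA_character_, length(labels))) {
  structure(list(labels = factor(labels, levels = c("O", "TS", "C")),
                 direction = directions,
                 K_eq = NA_real_, counts = table(labels)),
            class = "ensemble_partition")
}

test_that("the reference rule switches at a 20-degree native difference", {
  refs <- dihedral_reference(toy_sys()$open, toy_sys()$closed)
  ok <- !is.na(refs$delta)
  expect_identical(refs$rule[ok] == "single-average",
                   abs(refs$delta[ok]) < 20)
  # circular midpoint halves the wrapped difference
  mid_dist_O <- angular_distance(refs$ref_avg[ok], refs$alpha_O[ok])
  mid_dist_C <- angular_distance(refs$ref_avg[ok], refs$alpha_C[ok])
  expect_equal(mid_dist_O, mid_dist_C, tolerance = 1e-9)
})

test_that("p_folded hits its closed-form cases", {
  refs <- data.frame(residue = 1L, alpha_O = 10, alpha_C = 20, delta = 10,
                     rule = "single-average", ref_avg = 15)
  part <- mk_part(rep("O", 10))
  at_ref <- matrix(15, 10, 1)
  expect_equal(p_folded(at_ref, refs, part, window = 60)$p_O, 1.0)
  off90 <- matrix(15 + 90, 10, 1)
  expect_equal(p_folded(off90, refs, part, window = 60)$p_O, 0.0)
  seven <- matrix(c(rep(15, 7), rep(120, 3)), 10, 1)
  expect_equal(p_folded(seven, refs, part, window = 60)$p_O, 0.7)
})

test_that("three-candidate rule takes the best of O, C and midpoint", {
  refs <- data.frame(residue = 1L, alpha_O = 0, alpha_C = 100, delta = 100,
                     rule = "three-candidate", ref_avg = 50)
  part <- mk_part(rep("O", 10))
  # all frames near the C value: fraction within 20 deg of alpha_C is 1
  angles <- matrix(100, 10, 1)
  expect_equal(p_folded(angles, refs, part, window = 20)$p_O, 1.0)
  # frames split between candidates: per-frame listing oracle
  angles2 <- matrix(c(rep(0, 4), rep(100, 3), rep(180, 3)), 10, 1)
  best <- max(sapply(c(0, 100, 50), function(r)
    mean(angular_distance(angles2[, 1], r) <= 20)))
  expect_equal(p_folded(angles2, refs, part, window = 20)$p_O, best)
  expect_equal(best, 0.4)
})

test_that("TS foldedness is the unweighted mean of the two directions", {
  refs <- data.frame(residue = 1L, alpha_O = 0, alpha_C = 10, delta = 10,
                     rule = "single-average", ref_avg = 5)
  lab <- c("TS", "TS", "TS", "TS", "O")
  dirs <- c("closing", "closing", "opening", "opening", NA)
  angles <- matrix(c(5, 5, 5, 120, 5), 5, 1)  # closing 1.0, opening 0.5
  tb <- p_folded(angles, refs, mk_part(lab, dirs), window = 60)
  expect_equal(tb$p_TS_closing, 1.0)
  expect_equal(tb$p_TS_opening, 0.5)
  expect_equal(tb$p_TS, 0.75)
})

test_that("missing ensembles propagate as NA, never zero", {
  refs <- data.frame(residue = 1L, alpha_O = 0, alpha_C = 10, delta = 10,
                     rule = "single-average", ref_avg = 5)
  tb <- p_folded(matrix(5, 3, 1), refs, mk_part(rep("O", 3)), window = 60)
  expect_true(is.na(tb$p_C))
  expect_true(is.na(tb$p_TS))
  expect_equal(tb$p_O, 1.0)
})

test_that("wider windows never reduce foldedness (nested windows)", {
  an <- toy_analysis()
  refs <- dihedral_reference(toy_sys()$open, toy_sys()$closed)
  t60 <- p_folded(toy_angles(), refs, an$partition, window = 60)
  t20 <- p_folded(toy_angles(), refs, an$partition, window = 20)
  for (col in c("p_O", "p_C", "p_TS")) {
    ok <- !is.na(t60[[col]]) & !is.na(t20[[col]])
    expect_true(all(t60[[col]][ok] >= t20[[col]][ok] - 1e-12))
  }
})

test_that("a frozen native-O series is fully folded under the averaged reference", {
  refs <- dihedral_reference(toy_sys()$open, toy_sys()$closed)
  frames <- array(rep(toy_sys()$open$xyz, each = 4), c(4, 44, 3))
  angles <- dwgo:::pseudodihedrals_frames(frames)
  tb <- p_folded(angles, refs, mk_part(rep("O", 4)), window = 60)
  sa <- !is.na(tb$rule) & tb$rule == "single-average"
  within <- angular_distance(tb$alpha_O[sa], refs$ref_avg[sa]) <= 60
  expect_identical(tb$p_O[sa] == 1, within)
})

test_that("contact probabilities equal hand counts on a built trajectory", {
  ct <- data.frame(i = 1L, j = 4L, r0 = 5)
  # 10 frames: distance alternates native / stretched
  frames <- array(0, c(10, 4, 3))
  for (f in 1:10) {
    frames[f, 2, ] <- c(1, 0, 0); frames[f, 3, ] <- c(2, 0, 0)
    frames[f, 4, ] <- c(ifelse(f <= 6, 5, 9), 0, 0)
  }
  lab <- c(rep("O", 3), rep("C", 3), rep("TS", 4))
  dirs <- c(rep(NA, 6), "closing", "closing", "opening", "opening")
  tb <- contact_probabilities(frames, ct, mk_part(lab, dirs))
  expect_equal(tb$p_O, 1.0)        # frames 1-3 formed
  expect_equal(tb$p_C, 1.0)        # frames 4-6 formed
  expect_equal(tb$p_TS_closing, 0) # frames 7-8 stretched
  expect_equal(tb$p_TS, 0)
  ct2 <- data.frame(i = 1L, j = 4L, r0 = 2)
  expect_equal(contact_probabilities(frames, ct2, mk_part(lab, dirs))$p_O, 0)
})

test_that("classification follows the characteristic-contact inequalities exactly", {
  tb <- data.frame(i = 1:5, j = 6:10,
                   p_O = c(0.5, 0.9, 0.1, 0.65, 0.3),
                   p_C = c(0.5, 0.1, 0.9, 0.45, 0.2),
                   p_TS = c(0.5, 0.75, 0.6, 0.3, 0.1))
  cl <- classify(tb)
  expect_identical(cl$class, c("neither", "O", "C", "O", "neither"))
  # max(p_O, p_C) >= 0.5 is inclusive, so the first contact displays too
  expect_identical(cl$display, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(as.character(cl$p_TS_bin),
                   c("0.5-0.7", ">=0.7", "0.5-0.7", "<0.5", "<0.5"))
  # randomized table against a brute-force re-application of the rules
  set.seed(77)
  rnd <- data.frame(i = 1:50, j = 51:100, p_O = runif(50), p_C = runif(50),
                    p_TS = runif(50))
  got <- classify(rnd, delta = 0.2, display_floor = 0.5)
  for (k in 1:50) {
    expected <- if (rnd$p_O[k] - rnd$p_C[k] >= 0.2) "O" else
      if (rnd$p_C[k] - rnd$p_O[k] >= 0.2) "C" else "neither"
    expect_identical(got$class[k], expected)
    expect_identical(got$display[k], max(rnd$p_O[k], rnd$p_C[k]) >= 0.5)
  }
})

test_that("comparison tables subtract element-wise with inclusive display threshold", {
  set.seed(5)
  a <- classify(data.frame(i = 1:20, j = 21:40, p_O = runif(20),
                           p_C = runif(20), p_TS = runif(20)))
  expect_true(all(compare(a, a)$dp_O == 0))
  expect_false(any(compare(a, a)$display_O))
  b <- a
  b$p_O <- pmin(1, a$p_O + 0.1)  # exact boundary difference
  cmp <- compare(a, b)
  # display iff characteristic in either table and |dp| at (or above) 0.1,
  # with the boundary included
  expect_identical(cmp$display_O,
                   cmp$char_either & abs(cmp$dp_O) >= 0.1 - 1e-12)
  # element-wise subtraction oracle
  expect_equal(cmp$dp_O, a$p_O - b$p_O)
  expect_equal(cmp$dp_C, a$p_C - b$p_C)
})

test_that("comparison requires overlapping keys and ignores contact order", {
  a <- classify(data.frame(i = 1:3, j = 4:6, p_O = c(.9, .5, .2),
                           p_C = c(.1, .5, .8), p_TS = c(.5, .5, .5)))
  b <- classify(data.frame(i = 7:9, j = 10:12, p_O = 1:3 / 10,
                           p_C = 1:3 / 10, p_TS = 1:3 / 10))
  expect_error(compare(a, b), "disjoint")
  shuf <- a[c(3, 1, 2), ]
  expect_identical(compare(a, a)$dp_O, compare(shuf, a)$dp_O)
})

test_that("residue-table comparison differences display at |dp| >= 0.1", {
  ra <- data.frame(residue = 1:4, p_O = c(.9, .8, .7, .6),
                   p_C = c(.9, .8, .7, .6), p_TS = c(.9, .8, .7, .6))
  rb <- ra; rb$p_O <- ra$p_O - c(0, 0.05, 0.1, 0.4)
  cmp <- compare(ra, rb)
  expect_equal(cmp$dp_folded_O, c(0, 0.05, 0.1, 0.4))
  expect_identical(cmp$display_O, c(FALSE, FALSE, TRUE, TRUE))
})
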