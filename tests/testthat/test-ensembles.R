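test_that("basin finding recovers the modes of a known bimodal mixture", {
  set.seed(12)
  qc <- c(rnorm(3000, 0.2, 0.03), rnorm(7000, 0.8, 0.03))
  tbl <- data.frame(Q_O = runif(10000), Q_C = qc)
  b <- find_basins(tbl, bins = 40)
  width <- diff(range(qc)) / 40
  expect_lt(abs(b$center_O["Q_C"] - 0.2), width + 1e-9)
  expect_lt(abs(b$center_C["Q_C"] - 0.8), width + 1e-9)
  expect_true(any(b$in_O) && any(b$in_C))
  expect_false(any(b$in_O & b$in_C))
})

test_that("unimodal distributions are rejected with a calibration hint", {
  set.seed(13)
  tbl <- data.frame(Q_O = runif(5000), Q_C = rnorm(5000, 0.5, 0.05))
  expect_error(find_basins(tbl), "recalibrate")
  tbl2 <- data.frame(Q_O = runif(10), Q_C = rep(0.4, 10))
  expect_error(find_basins(tbl2), "degenerate|recalibrate")
})

test_that("transition paths are extracted exactly as hand-traced", {
  # label sequence O O x x C -> one closing path spanning the two x frames
  b <- list(in_O = c(TRUE, TRUE, FALSE, FALSE, FALSE),
            in_C = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  p <- transition_paths(b)
  expect_identical(p$n_transitions, 1L)
  expect_identical(p$segments$start, 3L)
  expect_identical(p$segments$end, 4L)
  expect_identical(p$segments$direction, "closing")
  expect_identical(p$on_path, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # O x O re-entry is not a transition
  b2 <- list(in_O = c(TRUE, FALSE, TRUE), in_C = c(FALSE, FALSE, FALSE))
  expect_identical(transition_paths(b2)$n_transitions, 0L)
  # C ... O gives an opening path
  b3 <- list(in_O = c(FALSE, FALSE, TRUE), in_C = c(TRUE, FALSE, FALSE))
  expect_identical(transition_paths(b3)$segments$direction, "opening")
})

test_that("transition-path extraction on the 1-D oracle matches a brute-force scan", {
  p <- one_d_double_well(4, diffusion = 1, timestep = 5e-3,
                         n_steps = 2e5, seed = 6)
  x <- brownian_1d(p)
  in_O <- x < -0.8; in_C <- x > 0.8
  mine <- transition_paths(list(in_O = in_O, in_C = in_C))
  # independent two-pointer scan over core-visit events
  state <- ifelse(in_O, "O", ifelse(in_C, "C", NA))
  visits <- which(!is.na(state))
  segs <- 0L
  for (k in seq_along(visits)[-1]) {
    if (state[visits[k]] != state[visits[k - 1]]) segs <- segs + 1L
  }
  expect_identical(mine$n_transitions, segs)
  expect_gt(segs, 5L)
})

test_that("time reversal swaps closing and opening and keeps path frames", {
  an <- toy_analysis()
  b <- an$basins
  fwd <- transition_paths(b)
  rev_b <- list(in_O = rev(b$in_O), in_C = rev(b$in_C))
  bwd <- transition_paths(rev_b)
  expect_identical(fwd$n_transitions, bwd$n_transitions)
  expect_identical(sum(fwd$segments$direction == "closing"),
                   sum(bwd$segments$direction == "opening"))
  expect_identical(rev(fwd$on_path), bwd$on_path)
})

test_that("separatrix p_TP equals a hand count on a 10-frame fixture", {
  tbl <- data.frame(Q_O = c(.9, .85, .7, .55, .5, .45, .35, .2, .15, .1),
                    Q_C = c(.1, .15, .3, .45, .5, .55, .65, .8, .85, .9))
  b <- list(in_O = tbl$Q_C <= 0.15, in_C = tbl$Q_C >= 0.85,
            center_O = c(Q_O = 0.875, Q_C = 0.125),
            center_C = c(Q_O = 0.125, Q_C = 0.875))
  p <- transition_paths(b)
  expect_identical(p$n_transitions, 1L)
  s <- optimize_separatrix(tbl, p, b, slopes = 1, n_intercepts = 21,
                           band = 0.08)
  # the best band around Q_C = Q_O + b contains only on-path frames
  in_band <- abs(tbl$Q_C - tbl$Q_O - s$intercept) / sqrt(2) <= 0.08
  expect_equal(s$p_TP, sum(p$on_path & in_band) / sum(in_band))
  expect_equal(s$p_TP, 1.0)  # every mid frame lies on the single path
})

test_that("the returned separatrix maximises p_TP over the grid", {
  an <- toy_analysis()
  s <- an$separatrix
  tbl <- an$coords; p <- an$paths; b <- an$basins
  slopes <- seq(-3, 3, length.out = 13)
  for (m in slopes) {
    r <- tbl$Q_C - m * tbl$Q_O
    for (bb in seq(min(r), max(r), length.out = 11)) {
      sO <- b$center_O["Q_C"] - m * b$center_O["Q_O"] - bb
      sC <- b$center_C["Q_C"] - m * b$center_C["Q_O"] - bb
      if (!(sO < 0 && sC > 0)) next
      inb <- abs(r - bb) / sqrt(1 + m^2) <= s$band
      if (!sum(inb)) next
      expect_lte(sum(p$on_path[inb]) / sum(inb), s$p_TP + 1e-12)
    }
  }
  expect_gte(s$p_TP, 0)
  expect_lte(s$p_TP, 1)
})

test_that("a trajectory confined to one basin cannot host a separatrix", {
  tbl <- data.frame(Q_O = runif(50, 0.8, 1), Q_C = runif(50, 0, 0.1))
  b <- list(in_O = rep(TRUE, 50), in_C = rep(FALSE, 50))
  p <- transition_paths(b)
  expect_identical(p$n_transitions, 0L)
  expect_error(optimize_separatrix(tbl, p, b), "no transition paths")
})

test_that("partition labels frames exhaustively and computes K_eq = N_C/N_O", {
  # synthetic 500-frame series: 400 closed-side, 100 open-side, no band hits
  tbl <- data.frame(Q_O = c(rep(0.9, 100), rep(0.1, 400)),
                    Q_C = c(rep(0.1, 100), rep(0.9, 400)))
  sep <- structure(list(slope = 0, intercept = 0.5, band = 0.02,
                        p_TP = 0.3,
                        in_band = rep(FALSE, 500),
                        side = ifelse(tbl$Q_C - 0.5 > 0, 1L, -1L)),
                   class = "separatrix")
  paths <- list(on_path = rep(FALSE, 500), direction = rep(NA_character_, 500))
  pa <- partition(tbl, sep, paths)
  expect_equal(pa$K_eq, 4.0)
  expect_identical(unname(pa$counts["TS"]), 0L)
  expect_identical(length(pa$labels), 500L)
  expect_false(anyNA(pa$labels))
})

test_that("partition matches a manual frame-by-frame assignment", {
  set.seed(44)
  n <- 20
  tbl <- data.frame(Q_O = runif(n), Q_C = runif(n))
  side <- ifelse(tbl$Q_C - 0.5 * tbl$Q_O - 0.2 > 0, 1L, -1L)
  in_band <- abs(tbl$Q_C - 0.5 * tbl$Q_O - 0.2) / sqrt(1.25) <= 0.1
  on_path <- rep(c(TRUE, FALSE), 10)
  dirs <- rep(NA_character_, n); dirs[on_path] <- "closing"
  sep <- structure(list(slope = 0.5, intercept = 0.2, band = 0.1, p_TP = 0.5,
                        in_band = in_band, side = side), class = "separatrix")
  pa <- partition(tbl, sep, list(on_path = on_path, direction = dirs))
  manual <- ifelse(in_band & on_path, "TS", ifelse(side > 0, "C", "O"))
  expect_identical(as.character(pa$labels), manual)
  expect_equal(pa$K_eq, sum(manual == "C") / sum(manual == "O"))
})

test_that("an all-closed partition flags K_eq as undefined", {
  tbl <- data.frame(Q_O = rep(0.1, 10), Q_C = rep(0.9, 10))
  sep <- structure(list(slope = 0, intercept = 0.5, band = 0.02, p_TP = 0,
                        in_band = rep(FALSE, 10), side = rep(1L, 10)),
                   class = "separatrix")
  expect_warning(pa <- partition(tbl, sep, list(on_path = rep(FALSE, 10),
                                                direction = rep(NA, 10))),
                 "undefined")
  expect_true(is.na(pa$K_eq))
})

test_that("K_eq from rates is a guarded quotient", {
  expect_equal(keq_from_rates(1, 1), 1.0)
  expect_error(keq_from_rates(0, 5), "positive")
  expect_error(keq_from_rates(5, -1), "positive")
})

test_that("TS frames are a subset of transition-path frames", {
  an <- toy_analysis()
  is_ts <- an$partition$labels == "TS"
  expect_true(all(an$paths$on_path[is_ts]))
  expect_true(all(an$partition$separatrix$in_band[is_ts]))
})

test_that("side-count K_eq agrees with core-count K_eq within the band fraction", {
  an <- toy_analysis()
  keq_side <- an$partition$K_eq
  keq_core <- sum(an$basins$in_C) / sum(an$basins$in_O)
  band_frac <- mean(an$separatrix$in_band | (!an$basins$in_O & !an$basins$in_C))
  expect_lt(abs(log(keq_side) - log(keq_core)),
            max(1.0, 5 * band_frac))
})

test_that("reweighting multiplier approaches exp(beta dEps) for sharp mixing", {
  # strong-mixing limit: wells far apart in energy, large beta_mix, so each
  # frame is fully owned by one well and the K_eq multiplier is analytic
  beta_T <- 1 / (0.0019872041 * 300)
  eo <- c(rep(0, 500), rep(50, 500))    # first half open-dominated
  ec <- c(rep(50, 500), rep(0, 500))
  isO <- seq_len(1000) <= 500
  k0 <- sum(!isO) / sum(isO)
  pred <- function(eps, bm = 50) {
    e0 <- dwgo:::mix_scalar(eo, ec, 0, bm)
    w <- exp(-beta_T * (dwgo:::mix_scalar(eo, ec, eps, bm) - e0))
    sum(w[!isO]) / sum(w[isO])
  }
  d_eps <- 0.5
  expect_equal(pred(d_eps) / k0, exp(beta_T * d_eps), tolerance = 1e-6)
})

test_that("calibration returns immediately when the target is already met", {
  m <- toy_model()
  cfg <- simulation_config(n_steps = 2e5, save_stride = 100, seed = 5)
  an <- analyze_run(m, run_langevin(m, config = cfg))
  got <- calibrate(m, an$partition$K_eq, cfg)
  expect_identical(got$iterations, 0L)
  expect_identical(got$eps_O, m$eps_O)
  expect_equal(got$K_eq, an$partition$K_eq)
})
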