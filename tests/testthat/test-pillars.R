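test_that("beam-theory spring constant and its scaling laws", {
  k <- compute_spring_constant(2e6, 5, 1)
  expect_equal(k, 3 * 2e6 * pi * 1e-24 / 64 / 125e-18 * 1000,
               tolerance = 1e-12)
  expect_lt(abs(k - 2.35), 0.01)            # the printed PDMS pillar value
  # d^4 and L^-3 scaling
  expect_equal(compute_spring_constant(2e6, 5, 2), 16 * k, tolerance = 1e-12)
  expect_equal(compute_spring_constant(2e6, 10, 1), k / 8, tolerance = 1e-12)
  expect_equal(compute_spring_constant(2e6, 10, 1), 0.2945, tolerance = 2e-4)
  expect_error(compute_spring_constant(-1, 5, 1), "positive")
})

test_that("pillar detection finds the lattice to subpixel accuracy", {
  ph <- generate_pillar_sequence(pillar_phantom_spec(
    n_rows = 4, n_cols = 4, n_frames = 1, seed = 21))
  rest <- detect_pillars(ph$frames[, , 1], pitch_um = 2, pixel_size_um = 0.1)
  expect_equal(nrow(rest), 16L)
  expect_equal(attr(rest, "completeness"), 1)
  truth <- ph$rest_positions[order(ph$rest_positions[, 1],
                                   ph$rest_positions[, 2]), ]
  expect_lt(max(abs(rest - truth)), 0.05)   # 0.5 px at 0.1 um/px

  expect_error(detect_pillars(matrix(0, 64, 64), 2, 0.1), "fewer than 4")
})

test_that("a missing pillar lowers completeness with a warning", {
  ph <- generate_pillar_sequence(pillar_phantom_spec(
    n_rows = 4, n_cols = 4, n_frames = 1, seed = 22))
  frame <- ph$frames[, , 1]
  # erase one interior pillar
  p <- ph$rest_positions[6, ]
  ri <- round(p[1] / 0.1) + 1; ci <- round(p[2] / 0.1) + 1
  frame[(ri - 8):(ri + 8), (ci - 8):(ci + 8)] <- 0
  expect_warning(rest <- detect_pillars(frame, 2, 0.1), "incomplete")
  expect_equal(nrow(rest), 15L)
  expect_lt(attr(rest, "completeness"), 1)
})

test_that("tracking recovers programmed steps and ramps within 20 nm", {
  nf <- 12; np <- 16
  disp <- array(0, c(np, nf, 2))
  disp[6, 7:nf, 1] <- 0.3                       # step at frame 7
  disp[11, , 2] <- seq(0, 0.425, length.out = nf)  # ramp
  ph <- generate_pillar_sequence(pillar_phantom_spec(
    n_rows = 4, n_cols = 4, n_frames = nf, displacements = disp, seed = 23))
  rest <- detect_pillars(ph$frames[, , 1], 2, 0.1)
  tr <- track_pillars(ph$frames, rest, 0.1, 2)
  ord <- order(ph$rest_positions[, 1], ph$rest_positions[, 2])
  truth <- ph$truth_displacements[ord, , ]
  err <- sqrt((tr$displacements[, , 1] - truth[, , 1])^2 +
              (tr$displacements[, , 2] - truth[, , 2])^2)
  expect_lt(max(err), 0.020)
  expect_false(any(tr$flagged))
})

test_that("drift correction zeroes references and preserves loads", {
  nf <- 15; np <- 16
  disp <- array(0, c(np, nf, 2))
  disp[6, , 1] <- seq(0, 0.4, length.out = nf)
  drift <- cbind(seq(0, 0.3, length.out = nf), seq(0, -0.2, length.out = nf))
  ph <- generate_pillar_sequence(pillar_phantom_spec(
    n_rows = 4, n_cols = 4, n_frames = nf, displacements = disp,
    drift = drift, seed = 24))
  rest <- detect_pillars(ph$frames[, , 1], 2, 0.1)
  tr <- track_pillars(ph$frames, rest, 0.1, 2)
  ord <- order(ph$rest_positions[, 1], ph$rest_positions[, 2])
  loaded <- which(ord == 6)
  refs <- setdiff(seq_len(np), loaded)
  trc <- correct_drift(tr, refs)
  expect_lt(max(abs(trc$displacements[refs, , ])), 0.020)
  expect_equal(max(trc$displacements[loaded, , 1]), 0.4, tolerance = 0.05)
  expect_error(correct_drift(tr, integer(0)), "empty")
  expect_warning(correct_drift(tr, c(1, 2)), "fewer than 3")
  # contaminated reference set: the loaded pillar drags the estimate
  expect_warning(correct_drift(tr, seq_len(np)), "loaded")
})

test_that("forces scale with k and peak is frame-order free", {
  nf <- 10; np <- 16
  disp <- array(0, c(np, nf, 2))
  disp[3, , 1] <- seq(0, 0.425, length.out = nf)
  ph <- generate_pillar_sequence(pillar_phantom_spec(
    n_rows = 4, n_cols = 4, n_frames = nf, displacements = disp,
    noise_sd = 0, seed = 25))
  rest <- detect_pillars(ph$frames[, , 1], 2, 0.1)
  tr <- track_pillars(ph$frames, rest, 0.1, 2)
  tr <- correct_drift(tr, which(apply(abs(
    ph$truth_displacements[order(ph$rest_positions[, 1],
                                 ph$rest_positions[, 2]), , ]), 1, max) == 0))
  fs <- forces_and_summary(tr, 2.35)
  ord <- order(ph$rest_positions[, 1], ph$rest_positions[, 2])
  expect_equal(fs$peaks[which(ord == 3)], 2.35 * 0.425, tolerance = 0.02)
  # zero-displacement pillars report (near) zero force
  expect_lt(max(fs$peaks[-which(ord == 3)]), 0.02)
  # linear in k
  fs2 <- forces_and_summary(tr, 4.70)
  expect_equal(fs2$peaks, 2 * fs$peaks, tolerance = 1e-12)
  # peak invariant under frame permutation
  set.seed(1)
  perm <- sample(nf)
  tr_perm <- tr
  tr_perm$displacements <- tr$displacements[, perm, ]
  fs3 <- forces_and_summary(tr_perm, 2.35)
  expect_equal(fs3$peaks, fs$peaks)
  # aggregate conventions
  two <- tr
  two$displacements[, , ] <- 0
  two$displacements[1, , 1] <- 1 / 2.35
  two$displacements[2, , 1] <- 3 / 2.35
  agg <- forces_and_summary(two, 2.35, cell_pillars = c(1, 2))
  expect_equal(agg$cell_force_nN, 2, tolerance = 1e-9)
  expect_error(forces_and_summary(tr, -1), "positive")
})
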