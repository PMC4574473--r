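test_that("a canonical T1 jump matches the whole-patch recomputation oracle", {
  ## geometry frozen (progress 0), topology flipped between frames
  quart <- canonical_t1(progress = 0)
  t_before <- triangulate_frame(quart$frames[[1]])
  t_after <- triangulate_frame(quart$frames[[2]])
  dt <- 1 / 12
  tc <- topological_contribution(
    t_before, t_after,
    events = list(t1 = data.frame(lost_a = 1, lost_b = 2,
                                  gained_a = 3, gained_b = 4)), dt = dt)
  ## oracle: brute-force mean elongation of each full patch
  qb <- mean_q_brute(t_before)
  qa <- mean_q_brute(t_after)
  expect_equal(unname(tc$T), unname(-(qa - qb) / dt), tolerance = 1e-12)
  expect_equal(unname(tc$total), unname(tc$T), tolerance = 1e-12)
  expect_length(tc$unassigned, 0)
  ## total tiled area is unchanged by the retriangulation
  expect_equal(sum(t_before$area), sum(t_after$area), tolerance = 1e-12)
  ## the reverse T1 at identical geometry is the exact negative
  tc_rev <- topological_contribution(
    t_after, t_before,
    events = list(t1 = data.frame(lost_a = 3, lost_b = 4,
                                  gained_a = 1, gained_b = 2)), dt = dt)
  expect_equal(unname(tc_rev$T), -unname(tc$T), tolerance = 1e-14)
})

test_that("intervals without events contribute nothing topological", {
  tis <- generate_tissue(synth_script(rows = 7, cols = 7, frames = 3,
                                      shear_xx = 0.05, seed = 51))
  dec <- run_decomposition(tis)
  expect_true(all(abs(dec$t_xx) < 1e-14))
  expect_true(all(abs(dec$c_xx) < 1e-14))
  expect_true(all(abs(dec$e_xx) < 1e-14))
})

test_that("a mirror-symmetric division has zero xy shear contribution", {
  ## divide a central cell of a symmetric lattice along the y axis: the
  ## configuration (and both daughters) map to themselves under the
  ## mirror y -> -y through the mother's center
  ev <- data.frame(frame = 2, type = "division", cell_a = NA, cell_b = NA,
                   cell = 41, axis = pi / 2)  # center of a 9x9 lattice
  tis <- generate_tissue(synth_script(rows = 9, cols = 9, frames = 3,
                                      events = ev, seed = 52))
  dec <- run_decomposition(tis)
  expect_equal(dec$c_xy[1], 0, tolerance = 1e-12)
  expect_gt(abs(dec$c_xx[1]), 0) # the xx part is genuinely nonzero
})

test_that("bond orientations follow the lattice geometry and rotate with it", {
  tis <- generate_tissue(synth_script(rows = 7, cols = 7, frames = 1,
                                      seed = 53))
  tri <- triangulate_frame(tis$frames[[1]])
  bo <- bond_orientation(tri)
  expect_gt(nrow(bo), 0)
  ## horizontal bonds: flanking triangle centers are stacked vertically
  cells <- tis$frames[[1]]$cells
  ia <- match(bo$a, cells$cell_id); ib <- match(bo$b, cells$cell_id)
  horiz <- abs(cells$y[ia] - cells$y[ib]) < 1e-9
  expect_true(any(horiz))
  expect_true(all(abs(bo$angle[horiz] - pi / 2) < 1e-9))
  ## rotating the frame shifts every connector angle by phi (mod pi)
  phi <- 0.4
  fr2 <- apply_map_frame(tis$frames[[1]],
                         matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)),
                                2, 2))
  bo2 <- bond_orientation(triangulate_frame(fr2))
  shift <- (bo2$angle - bo$angle) %% pi
  expect_true(all(pmin(abs(shift - phi), abs(shift - phi + pi),
                       abs(shift - phi - pi)) < 1e-9))
  ## matches a direct centroid computation on a perturbed lattice
  tisr <- generate_tissue(synth_script(rows = 6, cols = 6, frames = 1,
                                       disorder = 0.08, seed = 54))
  trir <- triangulate_frame(tisr$frames[[1]])
  bor <- bond_orientation(trir)
  i <- which.max(bor$a * 1000 + bor$b)
  pick <- trir[(trir$c1 %in% c(bor$a[i], bor$b[i])) +
                 (trir$c2 %in% c(bor$a[i], bor$b[i])) +
                 (trir$c3 %in% c(bor$a[i], bor$b[i])) == 2, ]
  cen <- cbind((pick$x1 + pick$x2 + pick$x3) / 3,
               (pick$y1 + pick$y2 + pick$y3) / 3)
  ang <- atan2(cen[2, 2] - cen[1, 2], cen[2, 1] - cen[1, 1]) %% pi
  expect_equal(bor$angle[i], ang, tolerance = 1e-12)
})

test_that("gain/loss angle histograms recover scripted anisotropy and null out noise", {
  ## scripted: losses of horizontal-connector bonds, gains near pi/2
  ev <- data.frame(frame = c(2, 3), type = "t1",
                   cell_a = c(28, 43), cell_b = c(29, 44),
                   cell = NA, axis = NA)
  tis <- generate_tissue(synth_script(rows = 8, cols = 8, frames = 4,
                                      events = ev, seed = 55))
  h <- gain_loss_histograms(tis)
  expect_equal(sum(h$lost_eff), 0, tolerance = 1e-12) # both sum to one
  expect_equal(sum(h$gained_eff), 0, tolerance = 1e-12)
  ## the lost connections pool in one bin (identical bond orientation)
  expect_equal(max(h$lost_eff), h$lost_eff[which.max(h$lost_eff)])
  expect_gt(max(h$lost_eff), 0.5)
  ## label permutation control: relabeling events as background zeroes out
  tri <- triangulate_frame(tis$frames[[1]])
  all_b <- bond_orientation(tri)
  set.seed(56)
  fake <- all_b[sample(nrow(all_b), 40), ]
  counts <- function(a) {
    h0 <- graphics::hist(a, breaks = h$breaks, plot = FALSE)$counts
    h0 / sum(h0)
  }
  eff <- counts(fake$angle) - counts(all_b$angle)
  expect_lt(max(abs(eff)), 0.15) # near-null within sampling error
  expect_error(gain_loss_histograms(tis, window = c(100, 101)), "no T1")
})

test_that("T1 rates count events per cell per hour", {
  ## static tissue: zero everywhere
  tis0 <- generate_tissue(synth_script(rows = 6, cols = 6, frames = 4,
                                       seed = 57))
  expect_true(all(t1_rate(tis0)$rate == 0))
  ## 2 T1s within a fully interior 1-h window over a 64-cell tissue
  ev <- data.frame(frame = c(2, 3), type = "t1",
                   cell_a = c(28, 43), cell_b = c(29, 44),
                   cell = NA, axis = NA)
  tis <- generate_tissue(synth_script(rows = 8, cols = 8, frames = 25,
                                      events = ev, seed = 58))
  r <- t1_rate(tis, window = 1)
  expect_equal(r$rate[r$time == 0.5], 2 / 64, tolerance = 1e-9)
})

test_that("correlation shear concentrates on triangles about to undergo a T1", {
  ## staggered per-row phases desynchronize the exchange waves, so at any
  ## interval only some row pairs are close to their T1s
  scr <- synth_script(rows = 13, cols = 12, frames = 23, dt = 1 / 12,
                      sliding = list(rate = 0.55, block = 1,
                                     phase = c(0, 0.11, 0.29, 0.41, 0.07)),
                      seed = 59)
  tis <- suppressWarnings(detect_events(generate_tissue(scr)))
  ca <- correlation_attribution(tis, horizon = 9L)
  ## partition adds to the total exactly (shared-mean convention)
  expect_equal(ca$subset_dxx + ca$rest_dxx, ca$total_dxx, tolerance = 1e-12)
  ## cumulated over the pre-exchange build-up, the flagged subset carries
  ## the majority of the correlation shear on a minority of the area
  sel <- ca$area_fraction > 0 & ca$area_fraction < 0.9
  expect_true(any(sel))
  cum_sub <- sum(ca$subset_dxx[sel]) ; cum_tot <- sum(ca$total_dxx[sel])
  expect_gt(abs(cum_sub) / (abs(cum_tot) + 1e-12), 0.5)
  expect_lt(mean(ca$area_fraction[sel]), 0.75)
  ## horizon truncation at the video end is flagged
  expect_true(all(ca$truncated[(nrow(ca) - 5):nrow(ca)]))
  ## no upcoming T1s: empty subset contributes nothing
  tis2 <- generate_tissue(synth_script(rows = 6, cols = 6, frames = 3,
                                       shear_xx = 0.04, seed = 60))
  ca2 <- correlation_attribution(tis2)
  expect_true(all(ca2$subset_dxx == 0))
  expect_true(all(ca2$area_fraction == 0))
})
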