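test_that("a synthetic tissue round-trips through the CSV schema", {
  tis <- generate_tissue(synth_script(rows = 6, cols = 6, frames = 3,
                                      shear_xx = 0.05, disorder = 0.05,
                                      seed = 31))
  path <- file.path(tempdir(), "rt_csv")
  write_tracked_tissue(tis, path, format = "csv")
  back <- read_tracked_tissue(path)
  expect_equal(length(back$frames), length(tis$frames))
  for (k in seq_along(tis$frames)) {
    a <- tis$frames[[k]]; b <- back$frames[[k]]
    expect_equal(b$cells$x, a$cells$x, tolerance = 1e-12)
    expect_equal(b$cells$area, a$cells$area, tolerance = 1e-12)
    expect_equal(b$neighbors$neighbor_id, a$neighbors$neighbor_id)
    expect_equal(b$vertex_cells$cell_id, a$vertex_cells$cell_id)
  }
  unlink(path, recursive = TRUE)
})

test_that("a synthetic tissue round-trips through the SQLite schema", {
  tis <- generate_tissue(synth_script(rows = 5, cols = 5, frames = 2,
                                      seed = 32))
  path <- file.path(tempdir(), "rt.sqlite")
  write_tracked_tissue(tis, path, format = "sqlite")
  back <- read_tracked_tissue(path)
  expect_equal(back$frames[[1]]$cells$x, tis$frames[[1]]$cells$x)
  expect_equal(back$frames[[2]]$neighbors, tis$frames[[2]]$neighbors,
               ignore_attr = TRUE)
  unlink(path)
})

test_that("missing tables and inconsistent event records are rejected", {
  tis <- generate_tissue(synth_script(rows = 5, cols = 5, frames = 2,
                                      seed = 33))
  path <- file.path(tempdir(), "broken_csv")
  write_tracked_tissue(tis, path, format = "csv")
  file.remove(file.path(path, "bonds.csv"))
  file.remove(file.path(path, "neighbors.csv"))
  expect_error(read_tracked_tissue(path), "missing tables")
  unlink(path, recursive = TRUE)
  ## recorded division with identical topology in both frames
  bad <- tis
  bad$lineage <- data.frame(mother = 1, daughter1 = 98, daughter2 = 99,
                            frame = 2)
  expect_error(validate_tissue(bad), "event/topology mismatch")
})

test_that("detect_events recovers a canonical T1 and scripted events exactly", {
  ## canonical quartet: diagonal contact flips between frames
  quart <- canonical_t1(progress = 1)
  blank <- quart
  blank$t1_events <- blank$t1_events[0, ]
  found <- detect_events(blank)
  expect_equal(nrow(found$t1_events), 1L)
  expect_setequal(c(found$t1_events$lost_a, found$t1_events$lost_b), c(1, 2))
  expect_setequal(c(found$t1_events$gained_a, found$t1_events$gained_b),
                  c(3, 4))
  ## scripted mixed events on a lattice
  ev <- data.frame(frame = c(2, 3, 4, 5),
                   type = c("t1", "division", "extrusion", "t1"),
                   cell_a = c(28, NA, NA, 43), cell_b = c(29, NA, NA, 44),
                   cell = c(NA, 32, 51, NA), axis = c(NA, pi / 4, NA, NA))
  tis <- generate_tissue(synth_script(rows = 8, cols = 8, frames = 6,
                                      events = ev, seed = 34))
  redet <- detect_events(tis)
  expect_equal(nrow(redet$t1_events), 2L)
  expect_equal(nrow(redet$extrusions), 1L)
  expect_equal(redet$extrusions$cell_id, 51)
  expect_equal(sort(redet$t1_events$frame), c(2, 5))
  ## a cell id disappearing without daughters is an extrusion
  expect_false(51 %in% tis$frames[[6]]$cells$cell_id)
})

test_that("area balance closes identically and reproduces scripted rates", {
  ## uniform dilation, no events: v equals the area term
  tis <- generate_tissue(synth_script(rows = 6, cols = 6, frames = 6,
                                      dilation = 0.12, seed = 35))
  ab <- area_balance(tis)
  expect_equal(ab$v, rep(0.12, nrow(ab)), tolerance = 1e-9)
  expect_equal(ab$da_term, ab$v, tolerance = 1e-12)
  expect_true(all(ab$kd == 0) && all(ab$ke == 0))
  expect_lt(max(abs(ab$closure)), 1e-10)
  ## static network: all terms zero
  ab0 <- area_balance(generate_tissue(synth_script(rows = 5, cols = 5,
                                                   frames = 3, seed = 36)))
  expect_true(all(abs(as.matrix(ab0[, c("v", "da_term", "kd", "ke")])) < 1e-12))
  ## with events the raw rates match the event counts
  ev <- data.frame(frame = 3, type = "division", cell_a = NA, cell_b = NA,
                   cell = 22, axis = 0)
  tis2 <- generate_tissue(synth_script(rows = 6, cols = 6, frames = 4,
                                       events = ev, seed = 37))
  ab2 <- area_balance(tis2)
  n0 <- nrow(tis2$frames[[2]]$cells)
  expect_equal(ab2$kd_raw[2], 1 / (n0 / 12), tolerance = 1e-12) # dt = 1/12 h
  expect_lt(max(abs(ab2$closure)), 1e-10)
})

test_that("variance ratio distinguishes independent from compensating contributions", {
  set.seed(38)
  ## independent contributions: ratio near 1
  finals <- cbind(rnorm(400), rnorm(400), rnorm(400))
  expect_equal(variance_ratio(finals), 1, tolerance = 0.15)
  ## perfectly anticorrelated pair: variance of the sum is zero
  c1 <- rnorm(10)
  vr <- variance_ratio(cbind(c1, -c1))
  expect_true(is.infinite(vr))
  expect_true(attr(vr, "degenerate"))
  ## strong compensation (correlation -0.95): matches Monte-Carlo oracle
  rho <- -0.95
  n <- 4000
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  vr2 <- variance_ratio(cbind(x, y))
  oracle <- (var(x) + var(y)) / var(x + y)  # direct evaluation
  expect_equal(vr2, oracle, tolerance = 1e-12)
  expect_gt(vr2, 10) # compensation makes the sum far more reproducible
  expect_error(variance_ratio(cbind(1, 2)[0, , drop = FALSE]), "replicates")
})
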