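test_that("Hill effect matches closed form at key doses and is monotone", {
  expect_equal(hill_effect(0, emax = 1, ec50 = 0.3, hill = 2), 0)
  expect_equal(hill_effect(0.3, emax = 1, ec50 = 0.3, hill = 2), 0.5)
  expect_equal(hill_effect(0.1, emax = 0.8, ec50 = 0.1, hill = 1), 0.4)
  expect_error(hill_effect(-1, 1, 0.3, 2), "negative")
  conc <- c(0, 0.03, 0.1, 0.3, 1, 10, 1e6)
  for (h in c(0.5, 1, 2, 4)) {
    e <- hill_effect(conc, emax = 0.9, ec50 = 0.3, hill = h)
    expect_true(all(diff(e) >= 0))
    expect_lt(abs(e[length(e)] - 0.9), 1e-3)
  }
})

test_that("rendered disc matches the rasterization oracle", {
  m <- render_organoid(50, jitter = 0)
  expect_equal(sum(m), sum(oracle_disc(50)))
  expect_lt(abs(sum(m) - pi * 50^2) / (pi * 50^2), 0.02)
})

test_that("branches enlarge the mask and keep it one 8-connected component", {
  set.seed(1)
  disc_area <- sum(render_organoid(20, jitter = 0))
  m <- render_organoid(20, n_branches = 8, branch_length_px = 30,
                       branch_width_px = 6, jitter = 0)
  expect_gt(sum(m), disc_area)
  lab <- segment_organoids(matrix(as.numeric(m), nrow(m), ncol(m)),
                           seg_config(threshold_method = "fixed",
                                      fixed_threshold = 0.5,
                                      min_area_px = 1,
                                      border_policy = "keep"))
  expect_equal(max(lab), 1L)
})

test_that("rendering is deterministic under a fixed seed", {
  set.seed(42)
  m1 <- render_organoid(25, 5, 20, 5, jitter = 0.3)
  set.seed(42)
  m2 <- render_organoid(25, 5, 20, 5, jitter = 0.3)
  expect_identical(m1, m2)
  row <- one_well()
  w1 <- render_well(row, synthetic_spec(canvas_px = 256,
                                        n_organoids_per_well = 4,
                                        log_area_mu = 6.5), seed = 9)
  w2 <- render_well(row, synthetic_spec(canvas_px = 256,
                                        n_organoids_per_well = 4,
                                        log_area_mu = 6.5), seed = 9)
  expect_identical(w1, w2)
})

test_that("ground truth conserves the label-image foreground exactly", {
  sp <- synthetic_spec(canvas_px = 384, n_organoids_per_well = 6,
                       log_area_mu = 7, death_fraction = 0.2)
  w <- render_well(one_well(), sp, seed = 21)
  expect_equal(sum(w$truth$area_px), sum(w$labels > 0))
  expect_equal(sum(w$truth$dead_px), sum(w$truth$death_fraction * w$truth$area_px))
  expect_true(all(w$truth$dead_px == round(w$truth$dead_px)))
})

test_that("dose effects steer branches, size and death as targeted", {
  drs <- list(AI = list(dose_response(1, 0.3, 2, "invasiveness")),
              GR = list(dose_response(0.8, 0.1, 2, "growth")),
              DE = list(dose_response(0.9, 0.1, 2, "death")))
  sp <- synthetic_spec(canvas_px = 448, n_organoids_per_well = 6,
                       log_area_mu = 7, dose_responses = drs)
  veh <- render_well(one_well(), sp, seed = 31)

  # saturating invasiveness suppression: no branches at all
  ai <- render_well(one_well("B01", "AI", 100, "treatment"), sp, seed = 32)
  expect_true(all(ai$truth$n_branches == 0))
  expect_gt(mean(veh$truth$n_branches), 2)

  # growth suppression shrinks median area
  gr <- render_well(one_well("B02", "GR", 100, "treatment"), sp, seed = 33)
  expect_lt(median(gr$truth$area_px), 0.5 * median(veh$truth$area_px))

  # death induction raises the realized dead fraction
  de <- render_well(one_well("B03", "DE", 100, "treatment"), sp, seed = 34)
  expect_gt(median(de$truth$death_fraction), 0.5)
  expect_lt(median(veh$truth$death_fraction), 0.2)
})

test_that("vehicle wells ignore dose-response entries", {
  drs <- list(DMSO = list(dose_response(1, 0.01, 2, "invasiveness")))
  sp <- synthetic_spec(canvas_px = 448, n_organoids_per_well = 6,
                       log_area_mu = 7, dose_responses = drs)
  veh <- render_well(one_well(compound_id = "DMSO", concentration_uM = 100),
                     sp, seed = 5)
  expect_gt(mean(veh$truth$n_branches), 0)
})

test_that("zero death fraction leaves the red channel noise-only", {
  sp <- synthetic_spec(canvas_px = 320, n_organoids_per_well = 4,
                       log_area_mu = 6.5, death_fraction = 0)
  w <- render_well(one_well(), sp, seed = 8)
  expect_true(all(w$truth$dead_px == 0))
  obj <- measure_organoids(w$labels, w$red)
  expect_true(all(obj$R == 0))
})

test_that("empirical log(area) follows the specified normal law", {
  set.seed(77)
  n <- 500; mu <- 8; sigma <- 0.4
  areas <- numeric(n)
  for (i in seq_len(n)) {
    a <- rlnorm(1, mu, sigma)
    areas[i] <- sum(render_organoid(max(2, sqrt(a / pi)), jitter = 0))
  }
  p <- suppressWarnings(ks.test(log(areas), "pnorm", mu, sigma)$p.value)
  expect_gt(p, 0.01)
})

test_that("generate_plate yields one image pair per well, reproducibly", {
  lay <- plate_layout(n_compounds = 20)
  expect_equal(nrow(lay), 96)
  sp <- synthetic_spec(canvas_px = 160, n_organoids_per_well = 2,
                       log_area_mu = 5.5, jitter = 0)
  d1 <- file.path(tempdir(), "plate1"); d2 <- file.path(tempdir(), "plate2")
  p1 <- generate_plate(lay, sp, seed = 3, dir = d1)
  p2 <- generate_plate(lay, sp, seed = 3, dir = d2)
  expect_equal(nrow(p1$manifest), 96)
  expect_length(list.files(d1, pattern = "_green\\.tif$"), 96)
  expect_length(list.files(d1, pattern = "_red\\.tif$"), 96)
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  unlink(c(d1, d2), recursive = TRUE)

  bad <- lay; bad$well_id[2] <- bad$well_id[1]
  expect_error(generate_plate(bad, sp, seed = 3), "duplicate well_id")
})

test_that("synthetic specs round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("canvas_px: 256",
               "n_organoids_per_well: 5",
               "log_area_mu: 7.2",
               "death_fraction: 0.1",
               "dose_responses:",
               "  C01:",
               "  - emax: 1.0",
               "    ec50: 0.3",
               "    hill: 2.0",
               "    target: invasiveness"), f)
  sp <- read_synthetic_spec(f)
  expect_s3_class(sp, "synthetic_spec")
  expect_equal(sp$canvas_px, 256)
  expect_equal(sp$dose_responses$C01[[1]]$ec50, 0.3)
  expect_equal(sp$dose_responses$C01[[1]]$target, "invasiveness")
  expect_equal(sp$jitter, 0.1)   # untouched defaults survive
  unlink(f)
})

test_that("positive-control wells carry the paclitaxel-like preset", {
  sp <- synthetic_spec(canvas_px = 448, n_organoids_per_well = 6,
                       log_area_mu = 7)
  veh <- render_well(one_well(), sp, seed = 11)
  pos <- render_well(one_well("H12", "paclitaxel", 1, "positive_control"),
                     sp, seed = 12)
  expect_lt(median(pos$truth$area_px), median(veh$truth$area_px))
  expect_gt(median(pos$truth$death_fraction),
            median(veh$truth$death_fraction))
  expect_lt(mean(pos$truth$n_branches), mean(veh$truth$n_branches))
})
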