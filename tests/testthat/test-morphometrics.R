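test_that("Theil-Sen recovers an exact line and matches a brute-force median", {
  x <- c(1, 2, 3, 5, 8, 13)
  fit <- theil_sen(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)

  set.seed(3)
  x <- runif(15); y <- 0.5 * x + rnorm(15, 0, 0.05)
  slopes <- c()
  for (i in 1:14) for (j in (i + 1):15)
    if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  fit <- theil_sen(x, y)
  expect_equal(fit$slope, median(slopes))
  expect_equal(fit$intercept, median(y - fit$slope * x))
})

test_that("complexity model requires enough size-spread objects", {
  expect_error(fit_complexity_model(data.frame(A = rep(100, 5), P = rep(40, 5))),
               "insufficient")
  expect_error(fit_complexity_model(data.frame(A = rep(100, 20), P = rep(40, 20))),
               "zero variance")
})

test_that("disc population obeys the half-power perimeter-area law", {
  radii <- seq(10, 200, by = 10)
  pop <- do.call(rbind, lapply(radii, function(r) measure_mask(oracle_disc(r))))
  fit <- fit_complexity_model(pop)
  expect_gte(fit$b, 0.45)
  expect_lte(fit$b, 0.55)
  cx <- complexity(pop$A, pop$P, fit)
  expect_true(all(cx$r > 0))
  expect_equal(min(cx$r), fit$eps)
})

test_that("discs sit in a narrow residual band that branched shapes exceed", {
  radii <- seq(10, 200, by = 10)
  pop <- do.call(rbind, lapply(radii, function(r) measure_mask(oracle_disc(r))))
  fit <- fit_complexity_model(pop)
  cx <- complexity(pop$A, pop$P, fit)
  expect_lt(diff(range(cx$r)), 0.1)
  set.seed(2)
  star <- measure_mask(render_organoid(20, 8, 30, 6, jitter = 0))
  expect_gt(complexity(star$A, star$P, fit)$r,
            median(cx$r) + 0.1)
})

test_that("adding branches to a disc strictly increases the residual", {
  radii <- seq(10, 200, by = 10)
  pop <- do.call(rbind, lapply(radii, function(r) measure_mask(oracle_disc(r))))
  fit <- fit_complexity_model(pop)
  set.seed(4)
  disc <- measure_mask(render_organoid(25, jitter = 0))
  star <- measure_mask(render_organoid(25, 8, 25, 6, jitter = 0))
  expect_gt(complexity(star$A, star$P, fit)$r,
            complexity(disc$A, disc$P, fit)$r)
})

test_that("residual complexity ranks shapes by their branchiness", {
  # reference model fitted across the round-to-stellate spectrum (discs of
  # all sizes plus the panel), as the pipeline fits on a whole experiment;
  # a fit on branched shapes alone drifts towards slope 1 and loses the
  # size-law anchor
  discs <- do.call(rbind, lapply(seq(10, 60, by = 2.5),
                                 function(r) measure_mask(oracle_disc(r))))
  set.seed(19)
  nb <- rep(0:12, length.out = 40)
  pop <- do.call(rbind, lapply(nb, function(k) {
    r <- runif(1, 15, 40)
    cbind(measure_mask(render_organoid(r, k, 1.5 * r, 4)), n_branches = k)
  }))
  fit <- fit_complexity_model(rbind(discs[, c("A", "P")], pop[, c("A", "P")]))
  cx <- complexity(pop$A, pop$P, fit)
  expect_gte(cor(cx$r, pop$n_branches, method = "spearman"), 0.8)
})

test_that("out-of-sample residuals below the floor are clamped and flagged", {
  pop <- do.call(rbind,
                 lapply(seq(10, 100, by = 10),
                        function(r) measure_mask(oracle_disc(r))))
  fit <- fit_complexity_model(pop)
  cx <- complexity(64, 5, fit)    # implausibly short perimeter
  expect_true(cx$clamped)
  expect_equal(cx$r, fit$eps)
})

test_that("dead ratio and roundness follow their closed forms", {
  expect_equal(dead_ratio(c(10, 200, 7), c(0, 100, 7)), c(0, 0.5, 1))
  expect_error(dead_ratio(10, 11))

  disc <- measure_mask(oracle_disc(100))
  rd <- roundness(disc$A, disc$P)
  expect_gte(rd, 85); expect_lte(rd, 100)

  line <- matrix(FALSE, 5, 104); line[3, 3:102] <- TRUE
  lm <- measure_mask(line)
  expect_equal(lm$A, 100L); expect_equal(lm$P, 100L)
  expect_lt(roundness(lm$A, lm$P), 15)

  set.seed(6)
  star <- measure_mask(render_organoid(25, 8, 25, 6, jitter = 0))
  disc25 <- measure_mask(render_organoid(25, jitter = 0))
  expect_lt(roundness(star$A, star$P), roundness(disc25$A, disc25$P))
})

test_that("log-residuals are closer to symmetric on an acinar-dominated mix", {
  set.seed(5)
  pop <- render_population(200, round_frac = 0.8)
  fit <- fit_complexity_model(pop)
  cx <- complexity(pop$A, pop$P, fit)
  expect_lt(abs(moment_skewness(cx$kappa)), abs(moment_skewness(cx$r)))
})

test_that("rho does not depend on the complexity model", {
  obj <- data.frame(object_id = 1:12, well_id = "A01",
                    A = round(seq(100, 1000, length.out = 12)),
                    P = round(3.2 * sqrt(seq(100, 1000, length.out = 12))),
                    R = round(seq(0, 300, length.out = 12)))
  f1 <- fit_complexity_model(obj)
  f2 <- f1; f2$b <- f1$b + 0.2; f2$c0 <- f1$c0 - 1
  expect_equal(morphometric_records(obj, f1)$rho,
               morphometric_records(obj, f2)$rho)
})

test_that("well aggregation takes medians and flags empty wells", {
  lay <- rbind(one_well("A01"), one_well("A02"), one_well("A03"))
  rec <- data.frame(object_id = 1:4,
                    well_id = c("A01", "A02", "A02", "A02"),
                    a = c(5, 1, 2, 9), r = 1, kappa = c(0, -1, 0, 1),
                    rho = c(0.2, 0.1, 0.3, 0.5), roundness_pct = 90,
                    clamped = FALSE)
  expect_warning(w <- aggregate_wells(rec, lay), "A03")
  expect_equal(nrow(w), 2)
  expect_equal(w$med_a[w$well_id == "A01"], 5)       # single object
  expect_equal(w$med_a[w$well_id == "A02"], 2)       # middle order statistic
  expect_equal(w$med_rho[w$well_id == "A02"], 0.3)
  expect_equal(w$n_objects, c(1, 3))
})

test_that("well median dead-ratio recovers the planted death fraction", {
  sp <- synthetic_spec(canvas_px = 1024, n_organoids_per_well = 40,
                       death_fraction = 0.3, jitter = 0)
  w <- suppressWarnings(render_well(one_well(), sp, seed = 3))
  lab <- segment_organoids(w$green, seg_config())
  obj <- measure_organoids(lab, w$red)
  expect_gte(nrow(obj), 30)
  expect_lt(abs(median(obj$R / obj$A) - 0.3), 0.02)
})
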