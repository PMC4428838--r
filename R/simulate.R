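#' Fractional Hill dose-response effect
#'
#' Standard Hill model for the fractional suppression (or induction) of a
#' phenotype parameter: `effect = emax * conc^hill / (ec50^hill + conc^hill)`.
#' The effect is 0 at zero dose, `emax/2` at `conc = ec50`, and approaches
#' `emax` at saturating dose.
#'
#' @param conc concentration in uM (vectorised, must be >= 0)
#' @param emax maximal fractional effect, in \[0, 1\]
#' @param ec50 half-maximal concentration in uM, > 0
#' @param hill Hill coefficient, > 0
#' @return fractional effect in \[0, emax\]
#' @export
hill_effect <- function(conc, emax, ec50, hill) {
  if (any(conc < 0)) stop("negative concentration")
  stopifnot(emax >= 0, emax <= 1, ec50 > 0, hill > 0)
  emax * conc^hill / (ec50^hill + conc^hill)
}

#' Dose-response descriptor for one phenotype axis
#'
#' @param emax maximal fractional effect in \[0, 1\]
#' @param ec50 half-maximal concentration (uM)
#' @param hill Hill coefficient
#' @param target phenotype axis the effect acts on: `"invasiveness"` scales
#'   branch number and length down, `"growth"` scales organoid radius down,
#'   `"death"` raises the dead-cell fraction towards its ceiling.
#' @return an object of class `dose_response`
#' @export
dose_response <- function(emax, ec50, hill = 1,
                          target = c("invasiveness", "growth", "death")) {
  target <- match.arg(target)
  stopifnot(emax >= 0, emax <= 1, ec50 > 0, hill > 0)
  structure(list(emax = emax, ec50 = ec50, hill = hill, target = target),
            class = "dose_response")
}

#' Generative parameters for a synthetic organoid screen
#'
#' Defines the population an in-silico well draws from: a log-normal law for
#' total structure area (log(Area) is treated as Gaussian), a Poisson branch
#' process for invasive protrusions, a baseline dead-cell fraction, imaging
#' intensities and noise, and per-compound dose-response effects.
#'
#' The area law governs the *total* rendered structure (core disc plus
#' branches): the core radius is solved from the target area given the branch
#' geometry, so suppressing invasion reshapes organoids without mechanically
#' shrinking them.
#'
#' @param n_organoids_per_well organoids drawn per well
#' @param log_area_mu,log_area_sigma natural-log area law (pixels^2)
#' @param baseline_branches Poisson mean of branch count for untreated
#'   invasive organoids
#' @param branch_length_factor branch length beyond the core rim, as a
#'   multiple of core radius
#' @param branch_width_factor branch width as a multiple of core radius
#' @param jitter boundary roughness in \[0, 1\]; 0 gives exact discs
#' @param death_fraction baseline dead-cell area fraction per organoid
#' @param death_max ceiling the death effect scales towards
#' @param dose_responses named list (by compound_id) of lists of
#'   [dose_response()] objects
#' @param positive_control fixed fractional effects applied to
#'   positive-control wells (paclitaxel-like: strong growth suppression and
#'   death induction), a list with elements `growth`, `invasiveness`, `death`
#' @param canvas_px square canvas side in pixels
#' @param fg,bg foreground / background intensity on a \[0, 1\] scale
#' @param snr foreground contrast over noise standard deviation
#' @param max_place_tries rejection-sampling attempts when placing an
#'   organoid before the best non-overlapping candidate so far is kept
#' @return an object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_organoids_per_well = 20,
                           log_area_mu = 8.0,
                           log_area_sigma = 0.4,
                           baseline_branches = 6,
                           branch_length_factor = 1.0,
                           branch_width_factor = 0.25,
                           jitter = 0.1,
                           death_fraction = 0.05,
                           death_max = 0.9,
                           dose_responses = list(),
                           positive_control = list(growth = 0.5,
                                                   invasiveness = 0.9,
                                                   death = 0.8),
                           canvas_px = 1024,
                           fg = 0.8, bg = 0.05, snr = 10,
                           max_place_tries = 200) {
  stopifnot(log_area_sigma >= 0,
            death_fraction >= 0, death_fraction <= 1,
            jitter >= 0, jitter <= 1,
            baseline_branches >= 0, canvas_px >= 64,
            fg > bg, snr > 0)
  structure(list(n_organoids_per_well = n_organoids_per_well,
                 log_area_mu = log_area_mu, log_area_sigma = log_area_sigma,
                 baseline_branches = baseline_branches,
                 branch_length_factor = branch_length_factor,
                 branch_width_factor = branch_width_factor,
                 jitter = jitter,
                 death_fraction = death_fraction, death_max = death_max,
                 dose_responses = dose_responses,
                 positive_control = positive_control,
                 canvas_px = canvas_px, fg = fg, bg = bg, snr = snr,
                 max_place_tries = max_place_tries),
            class = "synthetic_spec")
}

#' Read a synthetic screen specification from YAML
#'
#' The YAML mirrors the arguments of [synthetic_spec()]; `dose_responses`
#' entries are lists with fields `emax`, `ec50`, `hill`, `target`.
#'
#' @param path YAML file
#' @return a `synthetic_spec`
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$dose_responses)) {
    y$dose_responses <- lapply(y$dose_responses, function(drs)
      lapply(drs, function(d) do.call(dose_response, d)))
  }
  do.call(synthetic_spec, y)
}

#' Render one organoid as a binary mask
#'
#' Rasterises a core disc with optional radial branch protrusions (rectangle
#' capped by a half-disc at the tip) and optional low-order boundary
#' roughness. Branches start at the centre, so the mask is always a single
#' 8-connected component. The mask is returned on its own minimal canvas;
#' callers place it onto a well image.
#'
#' Uses the current RNG state (branch angles, roughness harmonics): seed the
#' session for reproducibility.
#'
#' @param radius_px core disc radius in pixels (>= 2)
#' @param n_branches number of radial branches
#' @param branch_length_px branch length beyond the core rim, pixels
#' @param branch_width_px branch width, pixels
#' @param jitter boundary roughness amplitude in \[0, 1\]; at 0 the core is
#'   the exact digital disc (pixel centres within `radius_px`)
#' @return logical matrix, `TRUE` inside the organoid
#' @export
render_organoid <- function(radius_px, n_branches = 0, branch_length_px = 0,
                            branch_width_px = max(3, 0.25 * radius_px),
                            jitter = 0) {
  stopifnot(radius_px >= 2, n_branches >= 0, branch_length_px >= 0,
            branch_width_px > 0, jitter >= 0, jitter <= 1)
  if (branch_length_px == 0) n_branches <- 0
  ext <- ceiling(radius_px * (1 + 0.3 * jitter) +
                 (if (n_branches > 0) branch_length_px + branch_width_px else 0)) + 2
  n <- 2L * as.integer(ext) + 1L
  cx <- ext + 1
  x <- matrix(rep(seq_len(n) - cx, times = n), n, n)   # row offsets
  y <- matrix(rep(seq_len(n) - cx, each = n), n, n)    # col offsets
  d <- sqrt(x^2 + y^2)

  if (jitter > 0) {
    theta <- atan2(y, x)
    coef <- stats::rnorm(8)
    s <- coef[1] * cos(2 * theta) + coef[2] * sin(2 * theta) +
         coef[3] * cos(3 * theta) + coef[4] * sin(3 * theta) +
         coef[5] * cos(4 * theta) + coef[6] * sin(4 * theta) +
         coef[7] * cos(5 * theta) + coef[8] * sin(5 * theta)
    s <- s / max(1, max(abs(s)))
    rloc <- radius_px * (1 + 0.3 * jitter * s)
    mask <- d <= rloc
  } else {
    mask <- d <= radius_px
  }

  if (n_branches > 0) {
    angles <- stats::runif(n_branches, 0, 2 * pi)
    L <- radius_px + branch_length_px
    hw <- branch_width_px / 2
    for (th in angles) {
      along <- x * cos(th) + y * sin(th)
      perp <- -x * sin(th) + y * cos(th)
      mask <- mask | (along >= 0 & along <= L & abs(perp) <= hw)
      tipd <- sqrt((x - L * cos(th))^2 + (y - L * sin(th))^2)
      mask <- mask | (tipd <= hw)
    }
  }
  mask
}

# Core radius giving a target total area for the branch geometry:
# total ~ r^2 * (pi + n_b * (len_f * width_f + pi * width_f^2 / 8)).
core_radius_for_area <- function(area, n_branches, len_f, width_f) {
  denom <- pi + n_branches * (len_f * width_f + pi * width_f^2 / 8)
  sqrt(area / denom)
}

# Effects (invasiveness, growth, death) for one layout row under a spec.
well_effects <- function(row, spec) {
  eff <- c(invasiveness = 0, growth = 0, death = 0)
  if (row$role == "positive_control") {
    pc <- spec$positive_control
    eff <- c(invasiveness = pc$invasiveness, growth = pc$growth,
             death = pc$death)
  } else if (row$role == "treatment") {
    drs <- spec$dose_responses[[row$compound_id]]
    for (dr in drs) {
      eff[dr$target] <- eff[dr$target] +
        hill_effect(row$concentration_uM, dr$emax, dr$ec50, dr$hill)
    }
    eff <- pmin(eff, 1)
  }
  eff
}

# Contiguous-ish dead sub-mask: k pixels of the organoid nearest (Euclidean)
# to a random interior seed pixel.
dead_submask <- function(mask, k) {
  if (k <= 0) return(mask & FALSE)
  idx <- which(mask)
  k <- min(k, length(idx))
  seed <- idx[sample.int(length(idx), 1)]
  n <- nrow(mask)
  ri <- ((idx - 1) %% n) + 1
  ci <- ((idx - 1) %/% n) + 1
  sr <- ((seed - 1) %% n) + 1
  sc <- ((seed - 1) %/% n) + 1
  ord <- order((ri - sr)^2 + (ci - sc)^2)
  out <- mask & FALSE
  out[idx[ord[seq_len(k)]]] <- TRUE
  out
}

#' Render one well: two-channel image pair plus ground truth
#'
#' Draws organoids from the spec's population, applies the dose-response
#' effects implied by the layout row (vehicle-control wells ignore all
#' effects; positive-control wells use the built-in paclitaxel-like preset),
#' places the structures without overlap on the canvas, and composes a green
#' (live, calcein-like) and red (dead, ethidium-like) channel with additive
#' Gaussian noise.
#'
#' @param row one-row data.frame with `well_id`, `compound_id`,
#'   `concentration_uM`, `cell_line`, `replicate`, `role`
#' @param spec a [synthetic_spec()]
#' @param seed integer seed for this well
#' @return list with `green`, `red` (numeric matrices in \[0,1\]), `labels`
#'   (integer ground-truth label matrix), and `truth` (data.frame with
#'   `organoid_id`, `well_id`, `area_px`, `n_branches`, `death_fraction`,
#'   `dead_px`, `placed` flag)
#' @export
render_well <- function(row, spec, seed) {
  stopifnot(is.data.frame(row), nrow(row) == 1)
  set.seed(seed)
  eff <- well_effects(row, spec)
  n <- spec$n_organoids_per_well
  cv <- spec$canvas_px

  areas <- stats::rlnorm(n, spec$log_area_mu, spec$log_area_sigma)
  nb <- stats::rpois(n, spec$baseline_branches * (1 - eff["invasiveness"]))
  len_f <- spec$branch_length_factor * (1 - eff["invasiveness"])
  if (len_f <= 0) nb[] <- 0L
  dfrac <- spec$death_fraction +
    eff["death"] * (spec$death_max - spec$death_fraction)

  labels <- matrix(0L, cv, cv)
  dead <- matrix(FALSE, cv, cv)
  truth <- vector("list", n)
  centres <- matrix(NA_real_, 0, 2)
  exts <- numeric(0)

  for (i in seq_len(n)) {
    r0 <- core_radius_for_area(areas[i], nb[i], len_f,
                               spec$branch_width_factor)
    r0 <- r0 * (1 - eff["growth"])
    if (r0 < 2) r0 <- 2
    bw <- max(3, spec$branch_width_factor * r0)
    bl <- len_f * r0
    m <- render_organoid(r0, nb[i], bl, bw, spec$jitter)
    half <- (nrow(m) - 1) / 2
    ext <- half + 1

    # rejection-sample a centre keeping structures apart and off the border
    lo <- ext + 1; hi <- cv - ext
    placed <- TRUE
    if (hi <= lo) { placed <- FALSE }
    if (placed) {
      best <- NULL; bestd <- -Inf
      for (t in seq_len(spec$max_place_tries)) {
        cand <- stats::runif(2, lo, hi)
        dmin <- if (nrow(centres) == 0) Inf else
          min(sqrt((centres[, 1] - cand[1])^2 +
                   (centres[, 2] - cand[2])^2) - (exts + ext))
        if (dmin > bestd) { bestd <- dmin; best <- cand }
        if (dmin > 2) break
      }
      placed <- bestd > 2
      if (placed) {
        ci <- round(best)
        rows <- (ci[1] - half):(ci[1] + half)
        cols <- (ci[2] - half):(ci[2] + half)
        sub <- labels[rows, cols]
        sub[m] <- i
        labels[rows, cols] <- sub
        centres <- rbind(centres, ci)
        exts <- c(exts, ext)
        a_px <- sum(m)
        k <- round(dfrac * a_px)
        dm <- dead_submask(m, k)
        dsub <- dead[rows, cols]
        dsub[dm] <- TRUE
        dead[rows, cols] <- dsub
        truth[[i]] <- data.frame(organoid_id = i, well_id = row$well_id,
                                 area_px = a_px, n_branches = nb[i],
                                 death_fraction = sum(dm) / a_px,
                                 dead_px = sum(dm), placed = TRUE)
      }
    }
    if (!placed) {
      truth[[i]] <- data.frame(organoid_id = i, well_id = row$well_id,
                               area_px = NA_integer_, n_branches = nb[i],
                               death_fraction = NA_real_, dead_px = NA_integer_,
                               placed = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  if (any(!truth$placed)) {
    warning(sprintf("well %s: %d organoid(s) not placed (packing limit)",
                    row$well_id, sum(!truth$placed)))
  }

  sd_noise <- (spec$fg - spec$bg) / spec$snr
  green <- spec$bg + spec$fg * (labels > 0) +
    matrix(stats::rnorm(cv * cv, 0, sd_noise), cv, cv)
  red <- spec$bg + spec$fg * dead +
    matrix(stats::rnorm(cv * cv, 0, sd_noise), cv, cv)
  green <- pmin(pmax(green, 0), 1)
  red <- pmin(pmax(red, 0), 1)

  list(green = green, red = red, labels = labels,
       truth = truth[truth$placed, , drop = FALSE])
}

#' Standard 96-well screen layout
#'
#' Compounds at the screen's four concentrations plus vehicle (DMSO) and
#' positive (paclitaxel) control wells, one cell line.
#'
#' @param n_compounds number of test compounds (named C01, C02, ...)
#' @param concentrations_uM tested concentrations
#' @param n_vehicle,n_positive numbers of control wells
#' @param cell_line cell line label
#' @param n_replicates replicate wells per compound x concentration
#' @return data.frame with columns `well_id`, `compound_id`,
#'   `concentration_uM`, `cell_line`, `replicate`, `role`
#' @export
plate_layout <- function(n_compounds = 20,
                         concentrations_uM = c(0.03, 0.1, 0.3, 1),
                         n_vehicle = 8, n_positive = 8,
                         cell_line = "PC-3", n_replicates = 1) {
  stopifnot(n_vehicle >= 1, n_positive >= 1)
  comp <- sprintf("C%02d", seq_len(n_compounds))
  trt <- expand.grid(compound_id = comp, concentration_uM = concentrations_uM,
                     replicate = seq_len(n_replicates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  trt$role <- "treatment"
  veh <- data.frame(compound_id = "DMSO", concentration_uM = 0,
                    replicate = seq_len(n_vehicle), role = "vehicle_control")
  pos <- data.frame(compound_id = "paclitaxel", concentration_uM = 1,
                    replicate = seq_len(n_positive), role = "positive_control")
  lay <- rbind(trt, veh, pos)
  lay$cell_line <- cell_line
  nw <- nrow(lay)
  rows <- LETTERS[((seq_len(nw) - 1) %/% 12) %% 8 + 1]
  cols <- (seq_len(nw) - 1) %% 12 + 1
  plate <- (seq_len(nw) - 1) %/% 96 + 1
  lay$well_id <- ifelse(plate > 1,
                        sprintf("P%d_%s%02d", plate, rows, cols),
                        sprintf("%s%02d", rows, cols))
  lay[, c("well_id", "compound_id", "concentration_uM", "cell_line",
          "replicate", "role")]
}

check_layout <- function(layout) {
  need <- c("well_id", "compound_id", "concentration_uM", "cell_line",
            "replicate", "role")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    stop("layout missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(layout$well_id))
    stop("duplicate well_id: ",
         paste(unique(layout$well_id[duplicated(layout$well_id)]),
               collapse = ", "))
  bad <- which(is.na(layout$well_id) | is.na(layout$role) |
               is.na(layout$concentration_uM) |
               !(layout$role %in% c("treatment", "vehicle_control",
                                    "positive_control")))
  if (length(bad))
    stop("corrupt layout row(s): ", paste(bad, collapse = ", "))
  invisible(layout)
}

#' Generate a full synthetic plate
#'
#' Renders every well of a layout under a spec. Per-well seeds are derived
#' deterministically from `seed`, so the plate is reproducible and
#' independent of evaluation order. Optionally writes 16-bit grayscale TIFFs
#' (`<well_id>_green.tif`, `<well_id>_red.tif`), the layout, the ground-truth
#' CSV and a manifest to `dir`.
#'
#' @param layout a plate layout data.frame (see [plate_layout()])
#' @param spec a [synthetic_spec()]
#' @param seed integer master seed
#' @param dir output directory, or `NULL` to keep everything in memory
#' @return list with `wells` (named list of [render_well()] results),
#'   `truth` (combined ground-truth data.frame), `layout`, and `manifest`
#' @export
generate_plate <- function(layout, spec, seed, dir = NULL) {
  check_layout(layout)
  wells <- vector("list", nrow(layout))
  names(wells) <- layout$well_id
  for (i in seq_len(nrow(layout))) {
    ws <- (seed * 7919L + i * 104729L) %% 2147483647L
    wells[[i]] <- render_well(layout[i, , drop = FALSE], spec, ws)
  }
  truth <- do.call(rbind, lapply(wells, `[[`, "truth"))
  rownames(truth) <- NULL
  manifest <- data.frame(well_id = layout$well_id,
                         green = paste0(layout$well_id, "_green.tif"),
                         red = paste0(layout$well_id, "_red.tif"))
  out <- list(wells = wells, truth = truth, layout = layout,
              manifest = manifest, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (w in layout$well_id) {
      tiff::writeTIFF(wells[[w]]$green, file.path(dir, paste0(w, "_green.tif")),
                      bits.per.sample = 16)
      tiff::writeTIFF(wells[[w]]$red, file.path(dir, paste0(w, "_red.tif")),
                      bits.per.sample = 16)
    }
    utils::write.csv(layout, file.path(dir, "layout.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  out
}
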