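readouts <- c(area = "med_a", complexity = "med_kappa", death = "med_rho")

#' Control anchors per stratum
#'
#' For each cell line (and batch, if a `batch` column is present) computes
#' the anchor medians of the three read-outs over vehicle-control wells
#' (`m_dmso`) and positive-control wells (`m_pax`): medians of the per-well
#' medians. At least two wells of each control role are required per
#' stratum.
#'
#' @param wells data.frame from [aggregate_wells()]
#' @return data.frame with one row per stratum x read-out: `cell_line`
#'   (and `batch`), `readout`, `m_dmso`, `m_pax`
#' @export
compute_anchors <- function(wells) {
  strat_cols <- intersect(c("cell_line", "batch"), names(wells))
  strata <- split(wells, wells[strat_cols], drop = TRUE)
  out <- lapply(names(strata), function(nm) {
    w <- strata[[nm]]
    veh <- w[w$role == "vehicle_control", , drop = FALSE]
    pos <- w[w$role == "positive_control", , drop = FALSE]
    if (nrow(veh) < 2 || nrow(pos) < 2)
      stop("missing controls in stratum '", nm,
           "': need >= 2 vehicle and >= 2 positive-control wells")
    res <- data.frame(readout = names(readouts),
                      m_dmso = vapply(readouts, function(col)
                        stats::median(veh[[col]]), numeric(1)),
                      m_pax = vapply(readouts, function(col)
                        stats::median(pos[[col]]), numeric(1)))
    for (sc in strat_cols) res[[sc]] <- w[[sc]][1]
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c(setdiff(names(out), c("readout", "m_dmso", "m_pax")),
          "readout", "m_dmso", "m_pax")]
}

#' Anchor-scale a read-out value
#'
#' Linear rescaling anchored on the plate controls:
#' `score = 100 * (x - m_dmso) / |m_pax - m_dmso|`. The vehicle control
#' maps to 0 and the positive control to -100 when it decreases the
#' read-out (area, complexity) or +100 when it increases it (cell death);
#' the absolute-value denominator is what lets one expression carry both
#' sign conventions. Scores are not clipped: treatments may exceed the
#' control levels.
#'
#' @param x value(s) on the read-out scale (well or treatment median)
#' @param m_dmso,m_pax anchor medians
#' @param tol minimal anchor separation; below it the positive control is
#'   ineffective in this stratum and scaling is undefined
#' @return anchored score(s)
#' @export
anchor_scale <- function(x, m_dmso, m_pax, tol = 1e-9) {
  if (abs(m_pax - m_dmso) <= tol)
    stop("degenerate anchors: |m_pax - m_dmso| <= tol (positive control ineffective)")
  100 * (x - m_dmso) / abs(m_pax - m_dmso)
}

#' Build anchored treatment profiles
#'
#' One profile per (compound, concentration, cell line): replicate wells are
#' combined by the median of their well-medians, then each read-out is
#' anchor-scaled against its stratum's controls. Control conditions appear
#' as profile rows too (vehicle scores 0 and the positive control scores
#' -100/+100 by construction).
#'
#' @param wells data.frame from [aggregate_wells()]
#' @param anchors data.frame from [compute_anchors()]
#' @return data.frame with `compound_id`, `concentration_uM`, `cell_line`,
#'   `role`, `s_area`, `s_complexity`, `s_death`, `n_wells`
#' @export
build_profiles <- function(wells, anchors) {
  key <- interaction(wells$compound_id, wells$concentration_uM,
                     wells$cell_line, drop = TRUE)
  groups <- split(wells, key)
  out <- lapply(groups, function(w) {
    an <- anchors[anchors$cell_line == w$cell_line[1], , drop = FALSE]
    sc <- vapply(names(readouts), function(ro) {
      a <- an[an$readout == ro, , drop = FALSE]
      anchor_scale(stats::median(w[[readouts[[ro]]]]), a$m_dmso, a$m_pax)
    }, numeric(1))
    data.frame(compound_id = w$compound_id[1],
               concentration_uM = w$concentration_uM[1],
               cell_line = w$cell_line[1], role = w$role[1],
               s_area = sc[["area"]], s_complexity = sc[["complexity"]],
               s_death = sc[["death"]], n_wells = nrow(w))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cell_line, out$compound_id, out$concentration_uM), ,
      drop = FALSE]
}
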