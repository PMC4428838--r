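#' Profile feature matrix
#'
#' Rows are treatments (compound x concentration), columns are
#' read-out x cell line. Treatments missing a cell-line block are imputed to
#' 0 (no effect) and flagged.
#'
#' @param profiles data.frame from [build_profiles()]
#' @param features read-out columns to use
#' @return list with `m` (numeric matrix, rownames `compound@conc`) and
#'   `imputed` (logical matrix of the same shape)
#' @export
profile_matrix <- function(profiles,
                           features = c("s_area", "s_complexity", "s_death")) {
  stopifnot(length(features) >= 1)
  rid <- paste0(profiles$compound_id, "@", profiles$concentration_uM)
  lines <- sort(unique(profiles$cell_line))
  rows <- unique(rid)
  cols <- as.vector(outer(features, lines, paste, sep = "|"))
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  imputed <- matrix(TRUE, length(rows), length(cols),
                    dimnames = list(rows, cols))
  for (i in seq_len(nrow(profiles))) {
    for (f in features) {
      cn <- paste(f, profiles$cell_line[i], sep = "|")
      m[rid[i], cn] <- profiles[[f]][i]
      imputed[rid[i], cn] <- FALSE
    }
  }
  if (any(imputed))
    warning(sum(imputed), " missing feature cell(s) imputed to 0")
  list(m = m, imputed = imputed)
}

#' Hierarchically cluster treatment profiles
#'
#' Euclidean distance with Ward linkage by default (alternatives: average,
#' complete). The dendrogram is deterministic: ties are resolved by the
#' input row order used by [stats::hclust()].
#'
#' @param profiles data.frame from [build_profiles()]
#' @param k number of clusters to cut into (or use `h`)
#' @param h cut height (overrides `k` when given)
#' @param linkage `"ward"`, `"average"` or `"complete"`
#' @param features read-out columns to use
#' @return list with `hc` (hclust), `assignments` (named integer vector),
#'   `matrix` (feature matrix), `imputed`
#' @export
cluster_profiles <- function(profiles, k = 3, h = NULL,
                             linkage = c("ward", "average", "complete"),
                             features = c("s_area", "s_complexity",
                                          "s_death")) {
  linkage <- match.arg(linkage)
  pm <- profile_matrix(profiles, features)
  if (nrow(pm$m) < 3) stop("need at least 3 profiles to cluster")
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  if (all(stats::dist(pm$m) == 0))
    warning("all profiles identical: single cluster")
  hc <- stats::hclust(stats::dist(pm$m), method = method)
  assignments <- if (is.null(h)) stats::cutree(hc, k = k)
                 else stats::cutree(hc, h = h)
  list(hc = hc, assignments = assignments, matrix = pm$m,
       imputed = pm$imputed)
}

#' Rule-based compound classification
#'
#' Classifies each anchored profile into the screen's phenotype classes.
#' With default thresholds (`T_strong = 60`, `T_weak = 25`, tolerance bands
#' 25): growth_inhibitory if `s_area <= -T_strong` (precedence over the
#' anti-invasive calls); anti_invasive_strong if `s_complexity <= -T_strong`
#' while area and death stay within their tolerance bands
#' (`s_area >= -T_area_tol`, `s_death <= T_death_tol`);
#' anti_invasive_weak likewise for `-T_strong < s_complexity <= -T_weak`;
#' otherwise inactive.
#'
#' @param profiles data.frame from [build_profiles()]
#' @param T_strong,T_weak,T_area_tol,T_death_tol class thresholds on the
#'   anchored score scale
#' @param cluster_ids optional assignments from [cluster_profiles()] to
#'   attach as a `cluster_id` column
#' @return data.frame `calls` with one class per profile row
#' @export
classify_compounds <- function(profiles, T_strong = 60, T_weak = 25,
                               T_area_tol = 25, T_death_tol = 25,
                               cluster_ids = NULL) {
  side_ok <- profiles$s_area >= -T_area_tol & profiles$s_death <= T_death_tol
  cls <- rep("inactive", nrow(profiles))
  cls[profiles$s_complexity <= -T_weak & profiles$s_complexity > -T_strong &
        side_ok] <- "anti_invasive_weak"
  cls[profiles$s_complexity <= -T_strong & side_ok] <- "anti_invasive_strong"
  cls[profiles$s_area <= -T_strong] <- "growth_inhibitory"
  calls <- data.frame(compound_id = profiles$compound_id,
                      concentration_uM = profiles$concentration_uM,
                      cell_line = profiles$cell_line,
                      class = cls)
  if (!is.null(cluster_ids)) {
    rid <- paste0(profiles$compound_id, "@", profiles$concentration_uM)
    calls$cluster_id <- unname(cluster_ids[rid])
  }
  calls
}

# hclust merge tree as nested lists (leaves carry labels), for JSON export.
hclust_to_list <- function(hc) {
  build <- function(i) {
    if (i < 0) return(list(leaf = hc$labels[-i]))
    list(height = hc$height[i],
         children = list(build(hc$merge[i, 1]), build(hc$merge[i, 2])))
  }
  build(nrow(hc$merge))
}

#' Export heatmap and matrix of anchored profiles
#'
#' Writes the profile matrix as CSV and renders a clustered heatmap with a
#' diverging palette centred at 0 (vehicle level); the positive control row
#' sits at -100 on the area/complexity columns and +100 on the death
#' column by construction.
#'
#' @param profiles data.frame from [build_profiles()]
#' @param png_file,csv_file output paths (`NULL` skips the figure or table)
#' @param cluster_rows cluster heatmap rows
#' @return (invisibly) the matrix that was written
#' @export
export_heatmap <- function(profiles, png_file = NULL, csv_file = NULL,
                           cluster_rows = TRUE) {
  pm <- profile_matrix(profiles)
  if (!is.null(csv_file))
    utils::write.csv(data.frame(treatment = rownames(pm$m), pm$m,
                                check.names = FALSE),
                     csv_file, row.names = FALSE)
  if (!is.null(png_file)) {
    lim <- max(abs(pm$m), 100)
    breaks <- seq(-lim, lim, length.out = 101)
    pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100)
    grDevices::png(png_file, width = 900, height = 200 + 18 * nrow(pm$m))
    pheatmap::pheatmap(pm$m, color = pal, breaks = breaks,
                       cluster_rows = cluster_rows && nrow(pm$m) >= 3,
                       cluster_cols = FALSE, silent = FALSE)
    grDevices::dev.off()
  }
  invisible(pm$m)
}
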