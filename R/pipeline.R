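#' Run a full in-silico screen
#'
#' Orchestrates simulate -> segment -> measure -> morphometrics -> anchor
#' scaling -> clustering/classification as one reproducible run. All stage
#' outputs are pure functions of (layout, spec, configs, seed); re-running
#' with the same seed reproduces every CSV byte-identically.
#'
#' The complexity reference model is fitted per cell line on all objects of
#' that line pooled (controls and treatments together).
#'
#' @param layout plate layout data.frame (see [plate_layout()])
#' @param spec a [synthetic_spec()]
#' @param seed integer master seed
#' @param seg segmentation config ([seg_config()])
#' @param k number of clusters for the dendrogram cut
#' @param thresholds named list overriding [classify_compounds()] thresholds
#' @param out_dir if given, writes objects.csv, records.csv, wells.csv,
#'   profiles.csv, calls.csv, heatmap_matrix.csv, heatmap.png,
#'   dendrogram.json and manifest.json there
#' @param write_images also write the well TIFFs under `out_dir/images`
#' @return list with `plate`, `objects`, `records`, `wells`, `anchors`,
#'   `profiles`, `clustering`, `calls`, `fits`
#' @export
run_screen <- function(layout, spec = synthetic_spec(), seed = 1,
                       seg = seg_config(), k = 3, thresholds = list(),
                       out_dir = NULL, write_images = FALSE) {
  check_layout(layout)
  stage <- "simulate"
  res <- tryCatch({
    plate <- generate_plate(layout, spec, seed,
                            dir = if (isTRUE(write_images) && !is.null(out_dir))
                              file.path(out_dir, "images") else NULL)

    stage <- "segment/measure"
    objects <- do.call(rbind, lapply(layout$well_id, function(w) {
      lab <- segment_organoids(plate$wells[[w]]$green, seg)
      measure_organoids(lab, plate$wells[[w]]$red, well_id = w)
    }))
    rownames(objects) <- NULL

    stage <- "morphometrics"
    obj_line <- layout$cell_line[match(objects$well_id, layout$well_id)]
    fits <- lapply(split(objects, obj_line), fit_complexity_model)
    records <- do.call(rbind, lapply(names(fits), function(cl) {
      morphometric_records(objects[obj_line == cl, , drop = FALSE],
                           fits[[cl]])
    }))
    rownames(records) <- NULL
    wells <- aggregate_wells(records, layout)

    stage <- "scaling"
    anchors <- compute_anchors(wells)
    profiles <- build_profiles(wells, anchors)

    stage <- "clustering"
    clustering <- cluster_profiles(profiles, k = k)
    calls <- do.call(classify_compounds,
                     c(list(profiles = profiles,
                            cluster_ids = clustering$assignments),
                       thresholds))

    list(plate = plate, objects = objects, records = records,
         wells = wells, anchors = anchors, profiles = profiles,
         clustering = clustering, calls = calls, fits = fits)
  }, error = function(e) {
    stop("screen run failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
    wr(res$objects, "objects.csv")
    wr(res$records, "records.csv")
    wr(res$wells, "wells.csv")
    wr(res$profiles, "profiles.csv")
    wr(res$calls, "calls.csv")
    export_heatmap(res$profiles,
                   png_file = file.path(out_dir, "heatmap.png"),
                   csv_file = file.path(out_dir, "heatmap_matrix.csv"))
    jsonlite::write_json(hclust_to_list(res$clustering$hc),
                         file.path(out_dir, "dendrogram.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg <- list(seed = seed, n_wells = nrow(layout),
                spec = spec[setdiff(names(spec), "dose_responses")],
                segmentation = unclass(seg), k = k,
                thresholds = thresholds,
                package_version = as.character(utils::packageVersion("organoscreen")))
    cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
    tf <- tempfile(); writeLines(cfg_json, tf)
    cfg$config_md5 <- unname(tools::md5sum(tf)); unlink(tf)
    jsonlite::write_json(cfg, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
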