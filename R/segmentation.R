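#' Segmentation configuration
#'
#' @param threshold_method `"otsu"` (per-image Otsu on the green channel) or
#'   `"fixed"`
#' @param fixed_threshold intensity threshold used when
#'   `threshold_method = "fixed"`
#' @param min_area_px objects smaller than this are removed (default 64,
#'   excludes debris-scale noise)
#' @param hole_fill fill internal holes before labeling
#' @param connectivity 4 or 8 (object labeling; border test is always
#'   4-neighbourhood)
#' @param border_policy `"drop"` removes objects touching the image border
#'   (truncated organoids bias both area and perimeter), `"keep"` retains
#'   them
#' @return an object of class `seg_config`
#' @export
seg_config <- function(threshold_method = c("otsu", "fixed"),
                       fixed_threshold = NULL,
                       min_area_px = 64,
                       hole_fill = TRUE,
                       connectivity = 8,
                       border_policy = c("drop", "keep")) {
  threshold_method <- match.arg(threshold_method)
  border_policy <- match.arg(border_policy)
  stopifnot(min_area_px >= 1, connectivity %in% c(4, 8))
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold required when threshold_method = 'fixed'")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_px = min_area_px, hole_fill = hole_fill,
                 connectivity = connectivity, border_policy = border_policy),
            class = "seg_config")
}

# Merge 4-connected labels that touch diagonally (union-find), yielding
# 8-connected components. EBImage::bwlabel is 4-connected.
merge_diagonal <- function(lab) {
  nl <- max(lab)
  if (nl < 2) return(lab)
  n <- nrow(lab); m <- ncol(lab)
  a1 <- lab[-n, -m]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-1, -m]; b2 <- lab[-n, -1]   # up-right diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  map <- c(0L, root)
  matrix(map[lab + 1L], n, m)
}

# Relabel 1..n in raster-scan order of each object's first pixel
# (column-major, matching R matrix storage) so labels are deterministic.
relabel <- function(lab) {
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  if (length(ids) == 0) return(lab)
  first <- vapply(ids, function(i) which(lab == i)[1], numeric(1))
  ord <- ids[order(first)]
  map <- integer(max(ids) + 1L)
  map[ord + 1L] <- seq_along(ord)
  matrix(map[as.integer(lab) + 1L], nrow(lab), ncol(lab))
}

#' Segment a green-channel projection into labeled organoids
#'
#' Thresholds the image (per-image Otsu by default), optionally fills holes,
#' labels connected components, removes objects below the minimum area, and
#' applies the border policy. A blank image (no foreground) yields an
#' all-zero label image with a warning, not an error.
#'
#' @param img 2D numeric matrix, non-negative intensities
#' @param cfg a [seg_config()]
#' @return integer label matrix (0 = background, objects labeled 1..n in
#'   raster-scan order)
#' @export
segment_organoids <- function(img, cfg = seg_config()) {
  stopifnot(is.matrix(img), all(img >= 0, na.rm = TRUE))
  thr <- if (cfg$threshold_method == "otsu") {
    EBImage::otsu(img, range = range(0, 1, max(img)))
  } else cfg$fixed_threshold
  bin <- img > thr
  if (!any(bin)) {
    warning("blank image: no foreground after threshold")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  if (cfg$hole_fill) bin <- EBImage::fillHull(bin) > 0
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  if (cfg$connectivity == 8) lab <- merge_diagonal(lab)
  sizes <- tabulate(lab[lab > 0])
  drop_ids <- which(sizes < cfg$min_area_px & sizes > 0)
  if (cfg$border_policy == "drop") {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop_ids <- union(drop_ids, edge[edge > 0])
  }
  if (length(drop_ids)) lab[lab %in% drop_ids] <- 0L
  relabel(lab)
}

# 4-neighbourhood border test: object pixel with at least one neighbour
# (up/down/left/right; off-image counts as background) carrying a different
# label. Returns a logical matrix.
border_pixels <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  up    <- rbind(0L, lab[-n, , drop = FALSE])
  down  <- rbind(lab[-1, , drop = FALSE], 0L)
  left  <- cbind(0L, lab[, -m, drop = FALSE])
  right <- cbind(lab[, -1, drop = FALSE], 0L)
  lab > 0 & (up != lab | down != lab | left != lab | right != lab)
}

# Otsu on the red channel with a contrast guard: if the two classes are not
# separated (no real red foreground) fall back to a fixed threshold.
choose_red_threshold <- function(red, fallback = 0.5) {
  thr <- EBImage::otsu(red, range = range(0, 1, max(red)))
  above <- red > thr
  if (!any(above) || all(above)) return(fallback)
  mu1 <- mean(red[above]); mu0 <- mean(red[!above]); s0 <- stats::sd(red[!above])
  # pure noise splits near its median: weak class contrast, large upper class
  if (!is.finite(s0) || (mu1 - mu0) < 6 * s0 || mean(above) > 0.25)
    fallback
  else thr
}

#' Measure segmented organoids
#'
#' For every labeled object, computes the paper-level raw quantities:
#' `A` — area as the number of pixels in the object; `P` — perimeter as the
#' number of border pixels (object pixels with at least one 4-neighbour
#' outside the object); `R` — number of object pixels whose red-channel
#' intensity exceeds `red_threshold`.
#'
#' @param lab integer label matrix from [segment_organoids()]
#' @param red co-registered red-channel matrix, or `NULL` (then `R = 0`)
#' @param red_threshold intensity cut for the red channel; `NULL` selects it
#'   per image by Otsu with a fixed fallback when no red foreground exists
#' @param well_id well identifier attached to every object
#' @return data.frame with columns `object_id`, `well_id`, `A`, `P`, `R`
#' @export
measure_organoids <- function(lab, red = NULL, red_threshold = NULL,
                              well_id = NA_character_) {
  stopifnot(is.matrix(lab))
  if (!is.null(red) && !all(dim(red) == dim(lab)))
    stop("red image dimensions do not match label image")
  nl <- max(lab)
  if (nl == 0)
    return(data.frame(object_id = integer(0), well_id = character(0),
                      A = integer(0), P = integer(0), R = integer(0)))
  A <- tabulate(lab[lab > 0], nbins = nl)
  bp <- border_pixels(lab)
  P <- tabulate(lab[bp], nbins = nl)
  if (is.null(red)) {
    R <- integer(nl)
  } else {
    if (is.null(red_threshold)) red_threshold <- choose_red_threshold(red)
    R <- tabulate(lab[lab > 0 & red > red_threshold], nbins = nl)
  }
  data.frame(object_id = seq_len(nl), well_id = well_id,
             A = as.integer(A), P = as.integer(P), R = as.integer(R))
}

#' Match segmented objects to ground-truth labels by IoU
#'
#' Greedy one-to-one matching of segmentation labels to ground-truth labels
#' by decreasing intersection-over-union; a ground-truth object counts as
#' recovered when its best available match reaches `iou_min`.
#'
#' @param seg,truth integer label matrices of equal size
#' @param iou_min IoU acceptance threshold
#' @return list with `n_truth`, `n_matched`, `fraction` and the per-pair
#'   `matches` data.frame (`truth_id`, `seg_id`, `iou`)
#' @export
match_to_truth <- function(seg, truth, iou_min = 0.7) {
  stopifnot(all(dim(seg) == dim(truth)))
  t_ids <- setdiff(unique(as.integer(truth)), 0L)
  sel <- truth > 0 | seg > 0
  tv <- truth[sel]; sv <- seg[sel]
  inter <- table(factor(tv[tv > 0 & sv > 0]), factor(sv[tv > 0 & sv > 0]))
  a_t <- tabulate(tv[tv > 0], nbins = max(1, max(tv)))
  a_s <- tabulate(sv[sv > 0], nbins = max(1, max(sv, 1)))
  if (length(inter) == 0 || length(t_ids) == 0)
    return(list(n_truth = length(t_ids), n_matched = 0L, fraction = 0,
                matches = data.frame(truth_id = integer(0),
                                     seg_id = integer(0), iou = numeric(0))))
  cand <- which(inter > 0, arr.ind = TRUE)
  ti <- as.integer(rownames(inter))[cand[, 1]]
  si <- as.integer(colnames(inter))[cand[, 2]]
  ov <- inter[cand]
  iou <- ov / (a_t[ti] + a_s[si] - ov)
  ord <- order(-iou)
  used_t <- used_s <- integer(0)
  keep <- logical(length(ord))
  for (k in ord) {
    if (iou[k] < iou_min) break
    if (!(ti[k] %in% used_t) && !(si[k] %in% used_s)) {
      keep[k] <- TRUE
      used_t <- c(used_t, ti[k]); used_s <- c(used_s, si[k])
    }
  }
  matches <- data.frame(truth_id = ti[keep], seg_id = si[keep],
                        iou = iou[keep])
  list(n_truth = length(t_ids), n_matched = nrow(matches),
       fraction = nrow(matches) / length(t_ids), matches = matches)
}
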