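#' Theil-Sen robust line fit
#'
#' Slope = median of all pairwise slopes, intercept = median of
#' `y - slope * x`. Exact (all pairs) up to `max_exact` points; beyond that a
#' deterministic evenly spaced subsample of `max_exact` points ordered by `x`
#' is used, keeping the fit reproducible without randomisation.
#'
#' @param x,y numeric vectors of equal length
#' @param max_exact largest n for the exact all-pairs computation
#' @return list with `slope` and `intercept`
#' @export
theil_sen <- function(x, y, max_exact = 1000) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(x) > max_exact) {
    ord <- order(x, y)
    keep <- ord[unique(round(seq(1, length(x), length.out = max_exact)))]
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  sel <- upper.tri(dx) & dx != 0
  if (!any(sel)) stop("zero variance in x: cannot fit")
  slope <- stats::median(dy[sel] / dx[sel])
  intercept <- stats::median(y - slope * x)
  list(slope = slope, intercept = intercept)
}

#' Fit the shape-complexity reference model
#'
#' Robustly regresses log-perimeter on log-area across a pooled set of
#' organoids (Theil-Sen), then lowers the intercept to the most circle-like
#' object so that every residual is strictly positive: the regression line
#' estimates the average perimeter at a given size, and the adjusted line is
#' the lower envelope representing a perfect circle. Residuals above it
#' measure shape complexity.
#'
#' Fit on all objects of one cell line and batch pooled (controls plus
#' treatments); at least 10 objects with `A >= 2` are required.
#'
#' @param objects data.frame with columns `A`, `P` (see
#'   [measure_organoids()])
#' @param eps positivity margin: the anchoring object's residual equals
#'   `eps` exactly (default 1e-6, keeps the log defined without distorting
#'   ranks)
#' @return object of class `complexity_fit` with elements `b` (slope),
#'   `c` (raw intercept), `c0` (adjusted intercept), `eps`, `n`
#' @export
fit_complexity_model <- function(objects, eps = 1e-6) {
  ok <- objects$A >= 2
  if (sum(ok) < 10) stop("insufficient objects for complexity model")
  a <- log(objects$A[ok])
  p <- log(objects$P[ok])
  if (stats::var(a) == 0) stop("zero variance in log(A): cannot fit")
  fit <- theil_sen(a, p)
  b <- fit$slope
  c_raw <- fit$intercept
  c0 <- min(p - b * a) - eps
  structure(list(b = b, c = c_raw, c0 = c0, eps = eps, n = sum(ok)),
            class = "complexity_fit")
}

#' @export
print.complexity_fit <- function(x, ...) {
  cat(sprintf("complexity_fit: log(P) = %.4f * log(A) + %.4f (adjusted %.4f), n = %d\n",
              x$b, x$c, x$c0, x$n))
  invisible(x)
}

#' Per-organoid shape complexity
#'
#' Residual of log-perimeter above the adjusted regression line:
#' `r = log(P) - (b * log(A) + c0)`, and its logarithm `kappa = log(r)`
#' (the log makes the residual distribution close to symmetric). For
#' in-sample objects `r > 0` by construction; out-of-sample objects that
#' fall below the adjusted line are clamped to `eps` and flagged.
#'
#' @param A,P area and perimeter (vectorised), `A >= 2`
#' @param fit a [fit_complexity_model()] result
#' @return data.frame with columns `r`, `kappa`, `clamped`
#' @export
complexity <- function(A, P, fit) {
  stopifnot(inherits(fit, "complexity_fit"), all(A >= 2))
  r <- log(P) - (fit$b * log(A) + fit$c0)
  clamped <- r <= 0
  r[clamped] <- fit$eps
  data.frame(r = r, kappa = log(r), clamped = clamped)
}

#' Dead-cell relative area
#'
#' Fraction of an organoid's area whose red (dead) signal is above
#' threshold: `rho = R / A`, a per-organoid cytotoxicity read-out.
#'
#' @param A area in pixels
#' @param R red-overlap area in pixels, `0 <= R <= A`
#' @return rho in \[0, 1\]
#' @export
dead_ratio <- function(A, R) {
  stopifnot(all(R >= 0), all(R <= A))
  R / A
}

#' Roundness percentage
#'
#' Isoperimetric ratio `100 * 4 * pi * A / P^2`, capped at 100. A perfect
#' circle scores 100; stellate invasive structures score low.
#'
#' @param A area in pixels
#' @param P perimeter in border pixels, `P >= 1`
#' @return roundness in (0, 100\]
#' @export
roundness <- function(A, P) {
  stopifnot(all(P >= 1))
  pmin(100, 100 * 4 * pi * A / P^2)
}

#' Per-object morphometric records
#'
#' Combines the three primary read-outs (log-area `a`, complexity `r` /
#' `kappa`, dead ratio `rho`) and the roundness percentage for every
#' measured object.
#'
#' @param objects data.frame from [measure_organoids()]
#' @param fit a [fit_complexity_model()] result
#' @return data.frame with `object_id`, `well_id`, `a`, `r`, `kappa`,
#'   `rho`, `roundness_pct`, `clamped`
#' @export
morphometric_records <- function(objects, fit) {
  cx <- complexity(objects$A, objects$P, fit)
  data.frame(object_id = objects$object_id, well_id = objects$well_id,
             a = log(objects$A), r = cx$r, kappa = cx$kappa,
             rho = dead_ratio(objects$A, objects$R),
             roundness_pct = roundness(objects$A, objects$P),
             clamped = cx$clamped)
}

#' Aggregate records to per-well medians
#'
#' Per-well medians of the three read-outs, joined with the plate layout
#' metadata. Wells present in the layout but without any measured object are
#' excluded with a warning.
#'
#' @param records data.frame from [morphometric_records()]
#' @param layout plate layout data.frame
#' @return data.frame with layout metadata plus `med_a`, `med_kappa`,
#'   `med_rho`, `n_objects`
#' @export
aggregate_wells <- function(records, layout) {
  check_layout(layout)
  empty <- setdiff(layout$well_id, unique(records$well_id))
  if (length(empty))
    warning("well(s) with no measured objects excluded: ",
            paste(empty, collapse = ", "))
  agg <- do.call(rbind, lapply(split(records, records$well_id), function(d) {
    data.frame(well_id = d$well_id[1],
               med_a = stats::median(d$a),
               med_kappa = stats::median(d$kappa),
               med_rho = stats::median(d$rho),
               n_objects = nrow(d))
  }))
  out <- merge(layout, agg, by = "well_id")
  out[order(match(out$well_id, layout$well_id)), , drop = FALSE]
}
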