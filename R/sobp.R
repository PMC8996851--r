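# Spread-out Bragg peak construction: non-negative least squares weighting
# of range-shifted pristine curves against a flat physical-dose target, and
# an iterative reweighting mode targeting flat biological dose (constant
# survival) across the plateau.

#' Solve SOBP component weights by non-negative least squares
#'
#' Finds weights w >= 0 minimizing || sum_i w_i curve_i - target ||_2
#' (Lawson-Hanson NNLS). All curves and the target must share one depth
#' grid. Components with duplicated shifter thickness are deduplicated
#' before solving.
#'
#' @param curves List of `depth_dose_curve`s on a common grid.
#' @param target A `depth_dose_curve` (>= 0) on the same grid.
#' @param thicknesses Optional shifter thicknesses (mm) labelling the
#'   curves; used for deduplication and reporting.
#' @param window Optional plateau window `c(lo, hi)` mm over which flatness
#'   is evaluated on the composed curve.
#' @param fit_window Optional `c(lo, hi)` mm restricting the least-squares
#'   residual to grid points inside it (ridge-filter design fits the
#'   plateau only; entrance-channel dose is left unconstrained). Default:
#'   fit the full grid.
#' @return Object of class `sobp_plan`: `weights`, `thicknesses`,
#'   `residual` (euclidean), `window`, `flatness` (max relative deviation
#'   from the window mean, if a window was given).
#' @export
solve_sobp_weights <- function(curves, target, thicknesses = NULL,
                               window = NULL, fit_window = NULL) {
  stopifnot(length(curves) >= 2L, inherits(target, "depth_dose_curve"))
  depth <- curves[[1L]]$depth
  for (cu in curves) {
    stopifnot(inherits(cu, "depth_dose_curve"))
    if (length(cu$depth) != length(depth) || any(cu$depth != depth))
      stop("all curves must share the target's depth grid")
  }
  if (length(target$depth) != length(depth) || any(target$depth != depth))
    stop("target grid does not match the component curves")
  if (is.null(thicknesses)) thicknesses <- seq_along(curves) - 1
  stopifnot(length(thicknesses) == length(curves))
  keep <- !duplicated(thicknesses)
  rows <- if (is.null(fit_window)) seq_along(depth)
          else which(depth >= fit_window[1] & depth <= fit_window[2])
  if (length(rows) < sum(keep))
    stop("fit window contains fewer grid points than components")
  A <- vapply(curves[keep], function(cu) cu$dose[rows], numeric(length(rows)))
  fit <- pracma::lsqnonneg(A, target$dose[rows])
  w <- numeric(length(curves))
  w[keep] <- fit$x
  plan <- structure(list(weights = w, thicknesses = thicknesses,
                         residual = sqrt(sum(fit$resid.norm)),
                         window = window, flatness = NA_real_),
                    class = "sobp_plan")
  if (!is.null(window)) {
    comp <- compose_sobp(plan, curves)
    plan$flatness <- sobp_flatness(comp, window)
  }
  plan
}

#' @export
print.sobp_plan <- function(x, ...) {
  cat(sprintf("<sobp_plan> %d components, residual %.4g%s\n",
              length(x$weights), x$residual,
              if (is.na(x$flatness)) ""
              else sprintf(", flatness %.2f%% over [%g, %g] mm",
                           100 * x$flatness, x$window[1], x$window[2])))
  print(data.frame(thickness_mm = x$thicknesses, weight = x$weights))
  invisible(x)
}

#' Compose a weighted sum of depth-dose curves
#'
#' Pointwise weighted sum of the component curves; with `record_sets`, the
#' per-component deposition records are scaled by their weight and merged
#' (zero-weight components dropped).
#'
#' @param plan An `sobp_plan`, or a bare non-negative weight vector.
#' @param curves List of `depth_dose_curve`s matching the weights.
#' @param record_sets Optional list of record data.frames, same length.
#' @return A `depth_dose_curve`, or (with `record_sets`) a list with
#'   `curve` and merged `records`.
#' @export
compose_sobp <- function(plan, curves, record_sets = NULL) {
  w <- if (inherits(plan, "sobp_plan")) plan$weights else plan
  if (any(w < 0)) stop("weights must be non-negative")
  if (length(w) != length(curves))
    stop("weight / curve count mismatch")
  dose <- Reduce(`+`, Map(function(wi, cu) wi * cu$dose, w, curves))
  curve <- depth_dose_curve(curves[[1L]]$depth, dose)
  if (is.null(record_sets)) return(curve)
  stopifnot(length(record_sets) == length(w))
  recs <- Map(function(wi, rs) {
    if (wi == 0) return(NULL)
    rs$edep <- rs$edep * wi
    rs
  }, w, record_sets)
  records <- do.call(rbind, recs)
  records <- records[order(records$voxel, records$ion, records$E), ]
  rownames(records) <- NULL
  list(curve = curve, records = records)
}

#' Flatness of a composed curve over a window
#'
#' Max relative deviation from the window mean, max|d - mean|/mean, over
#' grid points with `window[1] <= depth <= window[2]`.
#'
#' @param curve A `depth_dose_curve`.
#' @param window `c(lo, hi)` in mm.
#' @return Dimensionless flatness (0 = perfectly flat).
#' @export
sobp_flatness <- function(curve, window) {
  sel <- curve$depth >= window[1] & curve$depth <= window[2]
  if (!any(sel)) stop("empty plateau window")
  d <- curve$dose[sel]
  m <- mean(d)
  if (m <= 0) stop("zero mean dose over the window")
  max(abs(d - m)) / m
}

#' Build a spread-out Bragg peak from range-shifted beams
#'
#' Generates one pristine beam per shifter thickness, then solves component
#' weights for either a flat physical-dose plateau over `window`
#' (`mode = "physical"`) or a flat biological-dose plateau
#' (`mode = "biological"`, i.e. constant survival across the SOBP). The
#' biological mode iterates fixed-point reweighting of the physical target:
#' solve, evaluate the per-slice biological dose through the voxel actor,
#' rescale the target by mean(Dbio)/Dbio(z), repeat until the plateau
#' biological-dose spread falls below `bio_tol` or `max_iter` is reached.
#'
#' @param config Base [beam_config()] (unshifted component).
#' @param geom [phantom_geometry()].
#' @param thicknesses Shifter thicknesses, mm; 0 (the unshifted deepest
#'   peak) is prepended when absent.
#' @param window Plateau window, mm.
#' @param mode `"physical"` or `"biological"`.
#' @param table [survival_table()] (biological mode).
#' @param ref [reference_radiation()] (biological mode).
#' @param bio_tol Relative plateau biological-dose spread target.
#' @param max_iter Reweighting iterations cap.
#' @return List of class `sobp_result`: `plan`, `curve`, `records`,
#'   `components` (per-thickness beams), `geom`, and in biological mode
#'   `iterations` and `bio_spread`.
#' @export
build_sobp <- function(config = beam_config(),
                       geom = phantom_geometry(),
                       thicknesses = hibmc_shifter_thicknesses(),
                       window = c(149, 209),
                       mode = c("physical", "biological"),
                       table = NULL, ref = NULL,
                       bio_tol = 0.01, max_iter = 10L) {
  mode <- match.arg(mode)
  if (!0 %in% thicknesses) thicknesses <- c(0, thicknesses)
  thicknesses <- sort(unique(thicknesses))
  beams <- lapply(thicknesses, function(t)
    pristine_beam(apply_range_shifter(config, t), geom))
  curves <- lapply(beams, `[[`, "curve")
  record_sets <- lapply(beams, `[[`, "records")
  flat <- ifelse(geom$depth_grid >= window[1] & geom$depth_grid <= window[2],
                 1, 0)
  target <- depth_dose_curve(geom$depth_grid, flat)
  plan <- solve_sobp_weights(curves, target, thicknesses, window,
                             fit_window = window)
  out <- compose_sobp(plan, curves, record_sets)
  res <- list(plan = plan, curve = out$curve, records = out$records,
              components = beams, geom = geom, mode = mode)
  if (mode == "biological") {
    if (is.null(table) || is.null(ref))
      stop("biological mode requires a coefficient table and reference radiation")
    tdose <- target$dose
    best <- NULL
    for (it in seq_len(max_iter)) {
      rpt <- run_biodose_actor(res$records, table, ref, geom)
      bio <- rep(0, geom$n_slices)
      bio[rpt$voxel + 1L] <- rpt$dose_bio
      sel <- geom$depth_grid >= window[1] & geom$depth_grid <= window[2]
      spread <- (max(bio[sel]) - min(bio[sel])) / mean(bio[sel])
      if (is.null(best) || spread < best$bio_spread)
        best <- list(plan = res$plan, curve = res$curve,
                     records = res$records, bio_spread = spread,
                     iterations = it)
      if (spread < bio_tol) break
      ratio <- rep(1, geom$n_slices)
      ratio[sel] <- mean(bio[sel]) / pmax(bio[sel], 1e-12)
      tdose <- tdose * ratio
      target <- depth_dose_curve(geom$depth_grid, tdose)
      plan <- solve_sobp_weights(curves, target, thicknesses, window,
                                 fit_window = window)
      out <- compose_sobp(plan, curves, record_sets)
      res$plan <- plan; res$curve <- out$curve; res$records <- out$records
    }
    # keep the best evaluated iterate (the fixed-point map need not be
    # monotone in the spread)
    res$plan <- best$plan; res$curve <- best$curve
    res$records <- best$records
    res$bio_spread <- best$bio_spread; res$iterations <- best$iterations
  }
  structure(res, class = "sobp_result")
}

#' @export
print.sobp_result <- function(x, ...) {
  cat(sprintf("<sobp_result> mode %s, %d components, flatness %.2f%%\n",
              x$mode, length(x$plan$weights), 100 * x$plan$flatness))
  invisible(x)
}

#' HIBMC-style ridge-filter thickness set
#'
#' The 14 range-shifter thicknesses used to compose the 6 cm SOBP of the
#' 320 MeV/n carbon line. The published values are millimetres of the
#' aluminum ridge filter; the range arithmetic works in water-equivalent
#' thickness, so by default they are converted with the relative linear
#' stopping power of aluminum (~2.1), which is what lets 6-32 mm of filter
#' span a 6 cm plateau.
#'
#' @param water_equivalent Convert to mm of water (default) or return the
#'   printed aluminum thicknesses.
#' @param stopping_ratio Linear stopping-power ratio aluminum/water.
#' @return Numeric vector of thicknesses in mm.
#' @export
hibmc_shifter_thicknesses <- function(water_equivalent = TRUE,
                                      stopping_ratio = 2.1) {
  t <- c(6, 7, 10, 11, 12, 16, 19, 20, 21, 24, 26, 28, 30, 32)
  if (water_equivalent) t * stopping_ratio else t
}

#' Serialize / read an SOBP plan (thickness, weight pairs)
#'
#' @param plan An `sobp_plan`.
#' @param path Output file.
#' @export
write_sobp_plan <- function(plan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: shifter_thickness_mm weight", con)
  writeLines(sprintf("%.12g %.12g", plan$thicknesses, plan$weights), con)
  invisible(path)
}
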