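# Voxelized biological-dose engine: accumulate deposition records into
# dose-fraction-weighted (Kanai) mixed LQ coefficients per voxel, then
# derive physical dose, survival, biological dose and RBE.

#' Reference (X-ray) radiation coefficients
#'
#' The LQ coefficients of the reference photon beam used to express the
#' biological dose. The published reference values for the validation beam
#' are not available, so there is no default: both must be supplied.
#'
#' @param alpha_ref 1/Gy (> 0).
#' @param beta_ref 1/Gy^2 (> 0; a zero value selects the documented linear
#'   reference limit in [biological_dose()]).
#' @return Object of class `reference_radiation`.
#' @export
reference_radiation <- function(alpha_ref, beta_ref) {
  stopifnot(alpha_ref > 0, beta_ref >= 0)
  structure(list(alpha_ref = alpha_ref, beta_ref = beta_ref),
            class = "reference_radiation")
}

#' Create an empty voxel accumulator store
#'
#' Sparse store keyed by integer voxel index: only voxels that receive
#' energy are present. Each voxel carries the running totals Edep (MeV),
#' sum(Edep * alpha) and sum(Edep * beta), from which the dose-fraction
#' weighted mixed coefficients follow as ratios. Backed by a hashed
#' environment, so insertion and lookup are at worst logarithmic in the
#' occupied-voxel count.
#'
#' @return Object of class `voxel_store`.
#' @export
voxel_store <- function() {
  structure(list(env = new.env(parent = emptyenv(), hash = TRUE)),
            class = "voxel_store")
}

#' @export
print.voxel_store <- function(x, ...) {
  cat(sprintf("<voxel_store> %d occupied voxels\n", length(ls(x$env))))
  invisible(x)
}

#' Accumulate one deposition record into the store
#'
#' Looks up (alpha, beta) for the record's ion at its kinetic energy via
#' [interpolate_coefficients()], then updates the record's voxel: Edep is
#' added to the total and Edep * alpha, Edep * beta to the weighted sums.
#'
#' @param store A [voxel_store()] (updated by reference).
#' @param record List/row with `voxel`, `ion`, `E` (MeV/n), `edep` (MeV).
#' @param table A [survival_table()].
#' @param on_missing_ion `"error"` (default) or `"skip"` (drop the record
#'   with a warning).
#' @return The store, invisibly.
#' @export
accumulate <- function(store, record, table,
                       on_missing_ion = c("error", "skip")) {
  on_missing_ion <- match.arg(on_missing_ion)
  stopifnot(inherits(store, "voxel_store"))
  if (record$edep <= 0) stop("record must have positive deposited energy")
  co <- tryCatch(interpolate_coefficients(table, record$ion, record$E),
                 error = function(e) {
                   if (on_missing_ion == "skip") {
                     warning(conditionMessage(e), "; record skipped")
                     NULL
                   } else stop(e)
                 })
  if (is.null(co)) return(invisible(store))
  key <- as.character(record$voxel)
  cur <- store$env[[key]]
  if (is.null(cur)) cur <- c(edep = 0, sum_ea = 0, sum_eb = 0)
  cur <- cur + c(record$edep, record$edep * co$alpha, record$edep * co$beta)
  names(cur) <- c("edep", "sum_ea", "sum_eb")
  store$env[[key]] <- cur
  invisible(store)
}

#' Accumulate a whole record stream (vectorized)
#'
#' Batch equivalent of looping [accumulate()] over the rows of a record
#' data.frame; coefficients are interpolated per ion species in one call and
#' the weighted sums reduced with `rowsum`.
#'
#' @param store A [voxel_store()].
#' @param records data.frame with columns `voxel`, `ion`, `E`, `edep`.
#' @inheritParams accumulate
#' @return The store, invisibly.
#' @export
accumulate_records <- function(store, records, table,
                               on_missing_ion = c("error", "skip")) {
  on_missing_ion <- match.arg(on_missing_ion)
  stopifnot(inherits(store, "voxel_store"), is.data.frame(records))
  if (any(records$edep <= 0)) stop("records must have positive deposited energy")
  alpha <- beta <- numeric(nrow(records))
  keep <- rep(TRUE, nrow(records))
  for (nm in unique(records$ion)) {
    idx <- records$ion == nm
    co <- tryCatch(interpolate_coefficients(table, nm, records$E[idx]),
                   error = function(e) {
                     if (on_missing_ion == "skip") {
                       warning(conditionMessage(e), "; ",
                               sum(idx), " records skipped")
                       NULL
                     } else stop(e)
                   })
    if (is.null(co)) { keep[idx] <- FALSE; next }
    alpha[idx] <- co$alpha; beta[idx] <- co$beta
  }
  records <- records[keep, ]; alpha <- alpha[keep]; beta <- beta[keep]
  if (!nrow(records)) return(invisible(store))
  grp <- as.character(records$voxel)
  mat <- rowsum(cbind(records$edep, records$edep * alpha,
                      records$edep * beta), grp)
  for (i in seq_len(nrow(mat))) {
    key <- rownames(mat)[i]
    cur <- store$env[[key]]
    if (is.null(cur)) cur <- c(edep = 0, sum_ea = 0, sum_eb = 0)
    upd <- cur + mat[i, ]
    names(upd) <- c("edep", "sum_ea", "sum_eb")
    store$env[[key]] <- upd
  }
  invisible(store)
}

#' Mixed LQ coefficients of a voxel
#'
#' The dose-fraction weighted means alpha_mix = sum(f * alpha),
#' beta_mix = sum(f * beta) with f = Edep_component / Edep_total (Kanai
#' mixing), read off the accumulator ratios.
#'
#' @param store A [voxel_store()].
#' @param voxel Integer voxel index.
#' @return [lq_coefficients()] for the voxel.
#' @export
voxel_coefficients <- function(store, voxel) {
  cur <- store$env[[as.character(voxel)]]
  if (is.null(cur)) stop("voxel ", voxel, " not present in store")
  lq_coefficients(cur[["sum_ea"]] / cur[["edep"]],
                  cur[["sum_eb"]] / cur[["edep"]])
}

#' Physical dose of a voxel
#'
#' D = Edep / (density * volume) with the MeV -> J conversion; untouched
#' voxels have zero dose.
#'
#' @param store A [voxel_store()] (or a numeric Edep in MeV).
#' @param voxel Voxel index (ignored for numeric input).
#' @param volume_mm3 Voxel volume, mm^3 (> 0).
#' @param density g/cm^3 (> 0).
#' @return Dose in Gy.
#' @export
physical_dose <- function(store, voxel = NULL, volume_mm3, density = 1.0) {
  edep <- if (inherits(store, "voxel_store")) {
    cur <- store$env[[as.character(voxel)]]
    if (is.null(cur)) 0 else cur[["edep"]]
  } else store
  edep_to_dose(edep, volume_mm3, density)
}

#' Mixed-field cell survival
#'
#' \eqn{S_{mix}(D) = e^{-\alpha_{mix} D - \beta_{mix} D^2}}.
#'
#' @param coeff Mixed [lq_coefficients()] (e.g. from [voxel_coefficients()]).
#' @param D Dose, Gy (>= 0).
#' @return Survival fraction.
#' @export
mixed_survival <- function(coeff, D) lq_survival(coeff, D)

#' Biological dose of a mixed field
#'
#' The photon dose producing the same LQ effect as the mixed field:
#' \deqn{D_{bio} = \frac{-\alpha_{ref} + \sqrt{\alpha_{ref}^2 +
#'   4\beta_{ref}(\alpha_{mix} D + \beta_{mix} D^2)}}{2 \beta_{ref}}}
#' When the mixed coefficients equal the reference ones, Dbio = D exactly.
#' For beta_ref = 0 the linear-reference limit
#' \eqn{D_{bio} = (\alpha_{mix} D + \beta_{mix} D^2)/\alpha_{ref}} is used.
#'
#' @param coeff Mixed [lq_coefficients()].
#' @param D Physical dose, Gy (>= 0, vectorized).
#' @param ref A [reference_radiation()].
#' @return Biological dose in Gy.
#' @export
biological_dose <- function(coeff, D, ref) {
  stopifnot(inherits(ref, "reference_radiation"))
  if (any(D < 0)) stop("dose must be non-negative")
  effect <- coeff$alpha * D + coeff$beta * D^2
  if (ref$beta_ref == 0) return(effect / ref$alpha_ref)
  (-ref$alpha_ref + sqrt(ref$alpha_ref^2 + 4 * ref$beta_ref * effect)) /
    (2 * ref$beta_ref)
}

#' Relative biological effectiveness of a voxel field
#'
#' RBE = Dbio / D. Undefined at zero dose: returned as `NA` (reported as
#' missing, never as 0).
#'
#' @inheritParams biological_dose
#' @return Dimensionless RBE (NA where D = 0).
#' @export
rbe <- function(coeff, D, ref) {
  out <- rep(NA_real_, length(D))
  pos <- D > 0
  out[pos] <- biological_dose(coeff, D[pos], ref) / D[pos]
  out
}

#' RBE at a fixed survival level (RBE10, RBE50)
#'
#' Ratio of the reference dose to the mixed-field dose producing the same
#' survival `level`, both from the LQ inversion generalized to -ln(level).
#'
#' @param coeff Mixed [lq_coefficients()].
#' @param ref A [reference_radiation()].
#' @param level Survival fraction in (0, 1): 0.1 for RBE10, 0.5 for RBE50.
#' @return Dimensionless RBE at the given survival level.
#' @export
rbe_at_survival <- function(coeff, ref, level) {
  if (level <= 0 || level >= 1) stop("survival level must be in (0, 1)")
  d_ref <- d10_from_lq(lq_coefficients(ref$alpha_ref, ref$beta_ref), level)
  d_mix <- d10_from_lq(coeff, level)
  d_ref / d_mix
}

#' Relative difference in percent
#'
#' `100 * (reference - other) / reference`, reported as a magnitude; the
#' first argument is the reference (denominator).
#'
#' @param reference Reference value (non-zero).
#' @param other Compared value.
#' @return Relative difference in %, >= 0 (vectorized).
#' @examples
#' relative_difference(0.92, 0.77)  # 16.3
#' @export
relative_difference <- function(reference, other) {
  if (any(reference == 0)) stop("reference value must be non-zero")
  abs(100 * (reference - other) / reference)
}

#' Finalize a voxel store into a per-voxel report
#'
#' One row per occupied voxel, ordered by voxel index, with the standard
#' per-voxel column set: index, (x, y, z) coordinates (mm; the 1-D phantom
#' puts voxel centers on the beam axis), alpha_mix (1/Gy), beta_mix
#' (1/Gy^2), physical dose (Gy), biological dose (Gy) and RBE.
#'
#' @param store A [voxel_store()].
#' @param geom A [phantom_geometry()].
#' @param ref A [reference_radiation()].
#' @param density g/cm^3.
#' @return data.frame of class `biodose_report`.
#' @export
biodose_report <- function(store, geom, ref, density = 1.0) {
  stopifnot(inherits(store, "voxel_store"), inherits(geom, "phantom_geometry"))
  keys <- ls(store$env)
  idx <- sort(as.integer(keys))
  rows <- lapply(idx, function(v) {
    cur <- store$env[[as.character(v)]]
    co <- lq_coefficients(cur[["sum_ea"]] / cur[["edep"]],
                          cur[["sum_eb"]] / cur[["edep"]])
    D <- edep_to_dose(cur[["edep"]], geom$voxel_volume_mm3, density)
    db <- biological_dose(co, D, ref)
    data.frame(voxel = v, x = 0, y = 0,
               z = (v + 0.5) * geom$slice_mm,
               alpha_mix = co$alpha, beta_mix = co$beta,
               dose = D, dose_bio = db,
               rbe = if (D > 0) db / D else NA_real_)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(voxel = integer(), x = numeric(), y = numeric(),
                  z = numeric(), alpha_mix = numeric(),
                  beta_mix = numeric(), dose = numeric(),
                  dose_bio = numeric(), rbe = numeric())
  class(out) <- c("biodose_report", "data.frame")
  out
}

#' Run the voxel actor over a record stream
#'
#' Convenience wrapper: new store, [accumulate_records()], then
#' [biodose_report()].
#'
#' @inheritParams accumulate_records
#' @inheritParams biodose_report
#' @return A `biodose_report` data.frame.
#' @export
run_biodose_actor <- function(records, table, ref, geom = phantom_geometry(),
                              density = 1.0,
                              on_missing_ion = c("error", "skip")) {
  store <- voxel_store()
  accumulate_records(store, records, table, on_missing_ion)
  biodose_report(store, geom, ref, density)
}

#' Write a per-voxel report to a tab-separated ASCII file
#'
#' Fixed column order (index, x, y, z, alpha_mix, beta_mix, physical dose,
#' biological dose, RBE), `#` header, rows ordered by voxel index,
#' deterministic formatting; an empty store yields a header-only file.
#'
#' @param report A `biodose_report` (or the arguments of
#'   [biodose_report()] via `store`, `geom`, `ref`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_biodose_report <- function(report, path) {
  stopifnot(inherits(report, "biodose_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# voxel\tx_mm\ty_mm\tz_mm\talpha_mix_per_Gy\t",
                    "beta_mix_per_Gy2\tdose_Gy\tbiological_dose_Gy\tRBE"),
             con)
  if (nrow(report))
    writeLines(sprintf("%d\t%.12g\t%.12g\t%.12g\t%.12g\t%.12g\t%.12g\t%.12g\t%.12g",
                       report$voxel, report$x, report$y, report$z,
                       report$alpha_mix, report$beta_mix, report$dose,
                       report$dose_bio, report$rbe), con)
  invisible(path)
}
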