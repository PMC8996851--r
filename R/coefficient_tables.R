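# Survival-coefficient databases: per-ion (energy, alpha, beta) tables with
# provenance, whitespace-separated ASCII serialization and linear
# interpolation in kinetic energy per nucleon.

#' Survival-coefficient table
#'
#' Container for per-ion LQ coefficient databases: for each ion species a
#' data.frame with columns `energy` (MeV/n, strictly increasing), `alpha`
#' (1/Gy) and `beta` (1/Gy^2), plus provenance (model name, cell line).
#'
#' @param ions Named list of data.frames (names are ion species names).
#' @param model Provenance: model that produced the coefficients.
#' @param cell_line Provenance: cell line.
#' @return Object of class `survival_table`.
#' @export
survival_table <- function(ions, model = "unknown", cell_line = "unknown") {
  stopifnot(is.list(ions), length(ions) >= 1L, !is.null(names(ions)))
  for (nm in names(ions)) {
    df <- ions[[nm]]
    if (!is.data.frame(df) || !all(c("energy", "alpha", "beta") %in% names(df)))
      stop("ion '", nm, "': need columns energy, alpha, beta")
    if (nrow(df) < 2L)
      stop("ion '", nm, "': at least 2 grid points required")
    if (any(diff(df$energy) <= 0))
      stop("ion '", nm, "': energy grid must be strictly increasing")
    if (any(df$alpha < 0) || any(df$beta < 0))
      stop("ion '", nm, "': coefficients must be non-negative")
    ions[[nm]] <- df[c("energy", "alpha", "beta")]
  }
  structure(list(ions = ions, model = model, cell_line = cell_line),
            class = "survival_table")
}

#' @export
print.survival_table <- function(x, ...) {
  cat(sprintf("<survival_table> model %s, cell line %s\n", x$model,
              x$cell_line))
  for (nm in names(x$ions)) {
    df <- x$ions[[nm]]
    cat(sprintf("  %-9s %3d energies in [%.4g, %.4g] MeV/n, alpha in [%.4g, %.4g] /Gy\n",
                nm, nrow(df), min(df$energy), max(df$energy),
                min(df$alpha), max(df$alpha)))
  }
  invisible(x)
}

#' Write a survival-coefficient table to ASCII files
#'
#' One whitespace-separated file per ion under `path` (created if needed),
#' named `<ion>.txt`, with `#` header lines carrying ion identity, model and
#' cell line, then rows `energy alpha beta` at 12 significant digits.
#'
#' @param table A [survival_table()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(table, path) {
  stopifnot(inherits(table, "survival_table"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (nm in names(table$ions)) {
    ion <- ion_species(nm)
    df <- table$ions[[nm]]
    con <- file(file.path(path, paste0(nm, ".txt")), "w")
    writeLines(c(sprintf("# ion: %s %d", ion$symbol, ion$A),
                 sprintf("# model: %s", table$model),
                 sprintf("# cell_line: %s", table$cell_line),
                 "# columns: energy_MeV_per_n alpha_per_Gy beta_per_Gy2",
                 sprintf("%.12g %.12g %.12g", df$energy, df$alpha, df$beta)),
               con)
    close(con)
  }
  invisible(path)
}

#' Read a survival-coefficient table from ASCII files
#'
#' Reads every `*.txt` file under `path` (or the given files) in the dialect
#' written by [write_survival_table()]. Malformed rows, non-monotone energy
#' grids and negative coefficients are rejected with the offending file and
#' line number.
#'
#' @param path Directory containing `<ion>.txt` files, or a character vector
#'   of file paths.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.txt$", full.names = TRUE)
  else path
  if (length(files) == 0L) stop("no table files found under ", path)
  ions <- list()
  model <- cell_line <- "unknown"
  for (f in files) {
    lines <- readLines(f)
    if (length(lines) == 0L || all(grepl("^\\s*(#|$)", lines)))
      stop("empty coefficient table: ", f)
    hdr <- grep("^#", lines, value = TRUE)
    nm <- sub("^# ion:\\s*(\\S+).*$", "\\1", grep("^# ion:", hdr, value = TRUE)[1])
    if (is.na(nm) || !nzchar(nm))
      nm <- sub("\\.txt$", "", basename(f))
    m <- grep("^# model:", hdr, value = TRUE)
    if (length(m)) model <- sub("^# model:\\s*", "", m[1])
    cl <- grep("^# cell_line:", hdr, value = TRUE)
    if (length(cl)) cell_line <- sub("^# cell_line:\\s*", "", cl[1])
    rows <- which(!grepl("^\\s*(#|$)", lines))
    vals <- lapply(rows, function(i) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(tok))
      if (length(v) != 3L || anyNA(v))
        stop("malformed row in ", basename(f), " line ", i, ": '",
             lines[i], "'")
      v
    })
    df <- as.data.frame(do.call(rbind, vals))
    names(df) <- c("energy", "alpha", "beta")
    if (nrow(df) < 2L)
      stop("table ", basename(f), ": at least 2 grid points required")
    bad <- which(diff(df$energy) <= 0)
    if (length(bad))
      stop("non-increasing energy grid in ", basename(f), " line ",
           rows[bad[1] + 1L])
    neg <- which(df$alpha < 0 | df$beta < 0)
    if (length(neg))
      stop("negative coefficient in ", basename(f), " line ", rows[neg[1]])
    key <- tryCatch(ion_species(nm)$name, error = function(e) nm)
    ions[[key]] <- df
  }
  survival_table(ions, model = model, cell_line = cell_line)
}

#' Interpolate LQ coefficients at a kinetic energy
#'
#' Linear interpolation of alpha and beta separately in kinetic energy per
#' nucleon; queries at grid nodes return the node values exactly. Energies
#' outside the grid are clamped to the nearest node with a warning (never
#' extrapolated).
#'
#' @param table A [survival_table()].
#' @param ion Ion species (name or [ion_species()]).
#' @param E Kinetic energy per nucleon, MeV/n (vectorized).
#' @return [lq_coefficients()] with vector fields aligned with `E`.
#' @examples
#' tab <- survival_table(list(carbon = data.frame(
#'   energy = c(1, 2), alpha = c(0.2, 0.4), beta = 0.0615)))
#' interpolate_coefficients(tab, "carbon", 1.5)$alpha  # 0.3
#' @export
interpolate_coefficients <- function(table, ion, E) {
  stopifnot(inherits(table, "survival_table"))
  nm <- ion_species(ion)$name
  df <- table$ions[[nm]]
  if (is.null(df))
    stop("ion species '", nm, "' absent from coefficient table (has: ",
         paste(names(table$ions), collapse = ", "), ")")
  lo <- E < df$energy[1L]; hi <- E > df$energy[nrow(df)]
  if (any(lo | hi))
    warning(sprintf("%d quer%s outside [%g, %g] MeV/n for %s clamped to grid edge",
                    sum(lo | hi), if (sum(lo | hi) == 1L) "y" else "ies",
                    df$energy[1L], df$energy[nrow(df)], nm))
  a <- stats::approx(df$energy, df$alpha, xout = E, rule = 2)$y
  b <- stats::approx(df$energy, df$beta, xout = E, rule = 2)$y
  lq_coefficients(a, b)
}
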