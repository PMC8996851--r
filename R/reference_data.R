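#' Published HIBMC SOBP comparison values
#'
#' The published per-depth comparison values for the HIBMC 320 MeV/n
#' carbon-ion SOBP: biological dose predicted with the NanOx and mMKM
#' models, and RBE10/RBE50 from both models alongside the measured values
#' of Kagawa et al., at five depths (5, 101, 123, 145, 149 mm). These are
#' inputs for relative-difference arithmetic, not quantities this package
#' recomputes (the absolute values require the full beam-line Monte Carlo
#' and the original coefficient databases).
#'
#' @return data.frame with columns `depth_mm`, `dbio_nanox`, `dbio_mmkm`,
#'   `rbe10_kagawa`, `rbe10_nanox`, `rbe10_mmkm`, `rbe50_kagawa`,
#'   `rbe50_nanox`, `rbe50_mmkm`.
#' @export
published_sobp_comparison <- function() {
  path <- system.file("extdata", "reference", "hibmc_sobp_published.tsv",
                      package = "hadrondose", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
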