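#' Synthetic tension atlas shipped with the package
#'
#' `inst/extdata/tension_atlas_synthetic.csv` is a *synthetic stand-in* for
#' a literature compilation of interfacial tensions: the system names follow
#' published condensate and solid systems, but the tension ranges and
#' molecular weights are representative order-of-magnitude values chosen by
#' the package authors, not the published measurements. Condensate entries
#' span ~0.2-200 uJ/m^2 (with the high-tension entries being small
#' peptides), solids span ~0.4-12 mJ/m^2; the insulin crystal range
#' (2-12 mJ/m^2 against dilute solution) follows the published figures.
#' Use [read_tension_atlas()] to load it and [atlas_delta_g_min()] to
#' evaluate nucleation propensity.
#'
#' @return path to the CSV
#' @examples
#' atlas <- read_tension_atlas(tension_atlas_path())
#' head(atlas)
#' @export
tension_atlas_path <- function() {
  system.file("extdata", "tension_atlas_synthetic.csv", package = "condnuc")
}
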