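#' Default model configuration
#'
#' The bundled configuration (key-value YAML with nested sections) that
#' reproduces the reference mossy-fiber pearl-chain model verbatim: every
#' morphological, passive, channel and simulation parameter is mirrored as a
#' named entry.
#'
#' @return Nested configuration list.
#' @export
default_model_config <- function() {
  read_model_config(system.file("extdata", "mossy_fiber_default.yaml",
                                package = "pearlchain", mustWork = TRUE))
}

#' Read / write a model configuration file
#'
#' @param path YAML configuration file.
#' @return \code{read_model_config}: the configuration list;
#'   \code{write_model_config}: \code{path}, invisibly.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("morphology", "passive", "channels", "discretization")
  missing <- setdiff(needed, names(cfg))
  if (length(missing))
    stop("configuration is missing section(s): ",
         paste(missing, collapse = ", "))
  cfg
}

#' @rdname read_model_config
#' @param config configuration list.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Build a chain from a configuration list
#'
#' @param config configuration list as returned by
#'   \code{\link{read_model_config}} / \code{\link{default_model_config}}.
#' @return A \code{compartment_chain}.
#' @export
model_from_config <- function(config = default_model_config()) {
  mo <- config$morphology
  pa <- config$passive
  ch <- config$channels
  di <- config$discretization
  build_mossy_fiber_model(
    passive = passive_params(Cm = pa$Cm, Rm = pa$Rm, Ri = pa$Ri,
                             E_leak = pa$E_leak),
    n_boutons = mo$n_boutons,
    soma_diameter = mo$soma_diameter,
    axon_diameter = mo$axon$diameter, axon_length = mo$axon$length,
    bouton_diameter = mo$bouton_diameter,
    gna_axon = ch$Na$density_axon, gna_soma = ch$Na$density_soma,
    gk = ch$K$density,
    e_na = ch$Na$reversal, e_k = ch$K$reversal,
    gating_scheme = ch$gating_scheme,
    segments_per_um = di$segments_per_um)
}
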