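#' Default pipeline configuration
#'
#' The configuration consumed by [cli_main()] and [read_config()].  Keys:
#' `parameters` (overrides for the kinetic rates, see [read_parameters()]),
#' `xi_pairs` (list of `{xiK, xiV}`), `beta_grid`
#' (`{log2_min, log2_max, n}`), `xi_sweep`
#' (`{beta, which, log10_min, log10_max, n}`), `pulse`
#' (`{beta_low, beta_high, period, duty, cycles, resolution}`),
#' `truncation_tol`, `truncation_cap`, `seed`, `output_dir`, `plots`.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    parameters = list(),
    xi_pairs = list(list(xiK = 1, xiV = 1),
                    list(xiK = 1, xiV = 0.1),
                    list(xiK = 1, xiV = 10),
                    list(xiK = 0.1, xiV = 1),
                    list(xiK = 10, xiV = 1)),
    beta_grid = list(log2_min = -4, log2_max = 6, n = 11),
    xi_sweep = list(beta = 1, which = "V",
                    log10_min = -2, log10_max = 2, n = 9),
    pulse = list(beta_low = 0, beta_high = 16, period = 20,
                 duty = 0.5, cycles = 3, resolution = 100),
    truncation_tol = 1e-8,
    truncation_cap = 256,
    seed = 1,
    output_dir = ".",
    plots = FALSE
  )
}

#' Read a pipeline configuration file
#'
#' Plain-text YAML with the schema of [default_config()]; keys not present
#' take their defaults, unknown top-level keys are errors.
#'
#' @param path Path to the YAML config file.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  extra <- setdiff(names(raw), names(cfg))
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  cfg
}

.cfg_xi_pairs <- function(cfg) {
  lapply(cfg$xi_pairs, function(x)
    allostery_ratios(xiK = x$xiK, xiV = x$xiV))
}

.cfg_betas <- function(cfg) {
  g <- cfg$beta_grid
  default_beta_grid(g$log2_min, g$log2_max, g$n)
}
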