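#' Allosteric modulation ratios
#'
#' The two dimensionless ratios that quantify how the allosterically modified
#' conformation `A*` differs from the baseline conformation `A`.  K-type
#' allostery modulates substrate binding affinity: `xiK` is the ratio of
#' substrate association rates of `A*` versus `A`.  V-type allostery modulates
#' catalytic turnover: `xiV` is the ratio of the product-generation rates of
#' the bound complexes `A*S` versus `AS`.  Values above 1 correspond to
#' cooperative (activating) allostery, values below 1 to inhibition, and 1 to
#' a silent (neutral) modulation.
#'
#' @param xiK K-type ratio, must be positive.
#' @param xiV V-type ratio, must be positive.
#' @return An object of class `alo_ratios`: a named list with elements `xiK`
#'   and `xiV`.
#' @examples
#' allostery_ratios(xiK = 10, xiV = 0.1)
#' @export
allostery_ratios <- function(xiK = 1, xiV = 1) {
  if (!is.numeric(xiK) || length(xiK) != 1L || !is.finite(xiK) || xiK <= 0)
    stop("'xiK' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(xiV) || length(xiV) != 1L || !is.finite(xiV) || xiV <= 0)
    stop("'xiV' must be a single positive finite number", call. = FALSE)
  structure(list(xiK = as.numeric(xiK), xiV = as.numeric(xiV)),
            class = "alo_ratios")
}

#' @export
print.alo_ratios <- function(x, ...) {
  cat(sprintf("Allosteric ratios: xiK = %g (binding), xiV = %g (catalysis)\n",
              x$xiK, x$xiV))
  invisible(x)
}

# Canonical field order of a rate-parameter set; also the order in which the
# parameters are marshalled to the C++ SSA core.
.param_names <- c(
  "beta", "gammaS", "gammaP",
  "kA_on", "kA_off", "kAstar_on", "kAstar_off",
  "alpha", "alpha_star", "alphaS", "alphaS_star",
  "nu", "nu_star", "kB_on", "kB_off"
)

#' Default kinetic parameters of the allosteric signaling network
#'
#' All rates are expressed in units of the substrate degradation rate
#' `gammaS`, which sets the time scale and is fixed at 1.  The fixed baseline
#' is: `kA_on = kA_off = 1`, `kAstar_off = 1`, `alpha = 1` (A -> A*),
#' `alpha_star = 2` (A* -> A), `alphaS = 4` (AS -> A*S), `alphaS_star = 1`
#' (A*S -> AS), `nu = 1`, `kB_on = kB_off = 1`, `gammaP = 1`.  The allosteric
#' ratios enter as `kAstar_on = xiK` and `nu_star = xiV`, and the substrate
#' production rate `beta` is the user-controlled input.
#'
#' The asymmetry `alpha_star > alpha` makes the unbound baseline conformation
#' A more stable than A*, while `alphaS > alphaS_star` makes the bound
#' allosteric complex A*S more stable than AS: substrate binding stabilizes
#' the allosterically modified conformation, the hallmark thermodynamic
#' signature of allostery.
#'
#' @param xi An [allostery_ratios()] object.
#' @param beta Substrate production rate (per unit time), must be >= 0.
#' @return An object of class `alo_params`: a named list of the 15 kinetic
#'   rate constants.
#' @examples
#' default_parameters(allostery_ratios(xiK = 1, xiV = 10), beta = 4)
#' @export
default_parameters <- function(xi = allostery_ratios(), beta = 1) {
  if (!inherits(xi, "alo_ratios"))
    xi <- do.call(allostery_ratios, as.list(xi))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("'beta' must be a single finite number >= 0", call. = FALSE)
  p <- list(
    beta = as.numeric(beta),
    gammaS = 1, gammaP = 1,
    kA_on = 1, kA_off = 1,
    kAstar_on = xi$xiK, kAstar_off = 1,
    alpha = 1, alpha_star = 2,
    alphaS = 4, alphaS_star = 1,
    nu = 1, nu_star = xi$xiV,
    kB_on = 1, kB_off = 1
  )
  p <- p[.param_names]
  class(p) <- "alo_params"
  validate_parameters(p)
  p
}

#' Validate a rate-parameter set
#'
#' Checks that all 15 rate constants are present, finite and non-negative,
#' and that `gammaS` is strictly positive (it defines the unit of time).
#'
#' @param params An `alo_params` object (or named list with the same fields).
#' @return `params`, invisibly, with class `alo_params`.
#' @export
validate_parameters <- function(params) {
  missing <- setdiff(.param_names, names(params))
  if (length(missing))
    stop("missing rate parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(params), .param_names)
  if (length(extra))
    stop("unknown rate parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  v <- unlist(params[.param_names])
  if (!all(is.finite(v)) || any(v < 0))
    stop("all rates must be finite and >= 0; offending: ",
         paste(names(v)[!is.finite(v) | v < 0], collapse = ", "),
         call. = FALSE)
  # gammaS = 1 is the package's unit of time; zero is tolerated for
  # degenerate sub-models (e.g. a pure-birth substrate pool), negative never
  if (params$gammaS < 0)
    stop("'gammaS' must be >= 0", call. = FALSE)
  class(params) <- "alo_params"
  invisible(params)
}

#' Recover the allosteric ratios implied by a parameter set
#'
#' @param params An `alo_params` object.
#' @return An [allostery_ratios()] object with `xiK = kAstar_on / kA_on` and
#'   `xiV = nu_star / nu`.
#' @export
allostery_ratios_of <- function(params) {
  validate_parameters(params)
  if (params$kA_on <= 0 || params$nu <= 0)
    stop("ratios undefined: kA_on and nu must be > 0", call. = FALSE)
  allostery_ratios(xiK = params$kAstar_on / params$kA_on,
                   xiV = params$nu_star / params$nu)
}

#' @export
print.alo_params <- function(x, ...) {
  cat("Kinetic parameters (units of gammaS):\n")
  v <- unlist(x[.param_names])
  cat(paste0("  ", format(names(v), width = 12), " = ", format(v)),
      sep = "\n")
  invisible(x)
}

#' Read kinetic parameters from a flat key-value config file
#'
#' The file is plain-text YAML with one scalar per key; recognized keys are
#' the field names of [default_parameters()] (`beta`, `gammaS`, `gammaP`,
#' `kA_on`, `kA_off`, `kAstar_on`, `kAstar_off`, `alpha`, `alpha_star`,
#' `alphaS`, `alphaS_star`, `nu`, `nu_star`, `kB_on`, `kB_off`).  Keys not
#' present keep their default value; unknown keys and negative rates are
#' errors.
#'
#' @param path Path to the config file.
#' @return An `alo_params` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  extra <- setdiff(names(raw), .param_names)
  if (length(extra))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  p <- unclass(default_parameters())
  for (k in names(raw)) {
    val <- raw[[k]]
    if (!is.numeric(val) || length(val) != 1L)
      stop("parameter '", k, "' must be a single number", call. = FALSE)
    p[[k]] <- as.numeric(val)
  }
  class(p) <- "alo_params"
  validate_parameters(p)
  p
}

# Rates marshalled for the C++ SSA core, in .param_names order.
.param_vector <- function(params) {
  validate_parameters(params)
  unlist(params[.param_names], use.names = FALSE)
}
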