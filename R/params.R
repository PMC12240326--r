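#' Model parameters
#'
#' Construct the full parameter set of the reef model. All seventeen
#' constants are rates per year except the dimensionless handling times
#' (`eta_T`, `eta_M`), competition coefficients (`alpha_T`, `alpha_M`) and
#' the shelter weight `sigma`. Defaults are the base parameterisation used
#' throughout the analyses.
#'
#' @param i_C,i_T,i_M Propagule import rates for coral, turf and macroalgae
#'   (per year). `i_M = 0` encodes the assumption that macroalgae grow from
#'   recruits already present in turf rather than from external import.
#' @param b_C,b_T,b_M Lateral expansion rates of existing cover (per year);
#'   macroalgae expand more slowly than turf (`b_M < b_T`).
#' @param d_C Background coral mortality rate (per year).
#' @param gamma Rate at which uncropped turf matures into macroalgae
#'   (per year).
#' @param g_T,g_M Maximal herbivory rates on turf and macroalgae (per year);
#'   turf is consumed faster (`g_T > g_M`).
#' @param eta_T,eta_M Holling type II handling times for turf and
#'   macroalgae. Turf needs no handling (`eta_T = 0`).
#' @param alpha_T,alpha_M Competitive effect of turf and macroalgae on coral
#'   recruitment and growth, per unit cover; macroalgae compete harder
#'   (`alpha_M > alpha_T`).
#' @param r Herbivore intrinsic growth rate (per year), shared by all three
#'   functional groups.
#' @param sigma Weight of coral cover in the shared herbivore carrying
#'   capacity, in `[0, 1]`: capacity is `(1 - sigma) + sigma * C`.
#' @param f Fishing pressure, a constant per-capita loss rate applied
#'   equally to all herbivore groups (per year).
#'
#' @return An object of class `reef_params`: a named list with the
#'   seventeen parameters.
#' @examples
#' p <- reef_params()
#' p$g_T
#' reef_params(f = 0.3, sigma = 0.8)
#' @export
reef_params <- function(i_C = 0.05, i_T = 0.05, i_M = 0,
                        b_C = 0.3, b_T = 0.8, b_M = 0.5,
                        d_C = 0.1, gamma = 0.1,
                        g_T = 2, g_M = 1,
                        eta_T = 0, eta_M = 1,
                        alpha_T = 0.25, alpha_M = 0.5,
                        r = 1, sigma = 0.6, f = 0) {
  p <- list(i_C = i_C, i_T = i_T, i_M = i_M,
            b_C = b_C, b_T = b_T, b_M = b_M,
            d_C = d_C, gamma = gamma,
            g_T = g_T, g_M = g_M,
            eta_T = eta_T, eta_M = eta_M,
            alpha_T = alpha_T, alpha_M = alpha_M,
            r = r, sigma = sigma, f = f)
  validate_reef_params(p)
  structure(p, class = "reef_params")
}

#' @export
print.reef_params <- function(x, ...) {
  cat("<reef_params>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 8), " = ", format(v)),
      sep = "\n")
  invisible(x)
}

reef_param_names <- function() {
  c("i_C", "i_T", "i_M", "b_C", "b_T", "b_M", "d_C", "gamma",
    "g_T", "g_M", "eta_T", "eta_M", "alpha_T", "alpha_M",
    "r", "sigma", "f")
}

validate_reef_params <- function(p) {
  nm <- reef_param_names()
  if (!setequal(names(p), nm)) {
    stop("parameter set must contain exactly: ", paste(nm, collapse = ", "))
  }
  v <- unlist(p[nm])
  if (!all(is.finite(v))) stop("all parameters must be finite numbers")
  if (any(v < 0)) {
    stop("negative parameter(s): ",
         paste(nm[v < 0], collapse = ", "))
  }
  if (p$sigma > 1) stop("sigma must lie in [0, 1]")
  invisible(TRUE)
}

# Parameters in the fixed order expected by the compiled right-hand side.
param_vector <- function(params) {
  unlist(params[reef_param_names()])
}

#' Update parameters
#'
#' Return a copy of `params` with the named fields replaced. Unknown names
#' are an error, which catches typos in configuration files and sweeps.
#'
#' @param params A [reef_params()] object.
#' @param ... Named scalar replacements, e.g. `f = 0.3`.
#' @return A validated `reef_params` object.
#' @examples
#' update_params(reef_params(), f = 0.5, gamma = 0)
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(params)
  bad <- setdiff(names(repl), reef_param_names())
  if (length(bad) > 0 || is.null(names(repl)) || any(names(repl) == "")) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  }
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_reef_params(p)
  structure(p, class = "reef_params")
}

#' Read and write parameter files
#'
#' Parameters serialise to a flat YAML or JSON mapping keyed by symbol name
#' (`i_C`, `b_T`, `eta_M`, ...). On reading, keys present in the file
#' override the defaults; unknown keys are an error.
#'
#' @param path File path; format is chosen by extension (`.yml`, `.yaml`
#'   or `.json`).
#' @param params A [reef_params()] object (for writing).
#' @return `read_params()` returns a `reef_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported parameter file extension: .", ext)
  )
  if (length(vals) == 0) return(reef_params())
  do.call(update_params, c(list(reef_params()), as.list(vals)))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "reef_params"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yml = ,
    yaml = yaml::write_yaml(unclass(params), path),
    json = jsonlite::write_json(unclass(params), path,
                                auto_unbox = TRUE, digits = NA),
    stop("unsupported parameter file extension: .", ext)
  )
  invisible(path)
}
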