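# Shared helpers: typed conditions, distribution specs, small utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Typed errors
#'
#' The pipeline distinguishes configuration errors (bad parameters),
#' format errors (malformed input files) and validation/analysis errors
#' (well-formed input violating a contract). The CLI maps these classes
#' to distinct exit codes.
#'
#' @param msg message string
#' @param class extra condition class
#' @noRd
grb_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "grb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error   <- function(msg) grb_stop(msg, "grb_config_error")
format_error   <- function(msg) grb_stop(msg, "grb_format_error")
analysis_error <- function(msg) grb_stop(msg, "grb_analysis_error")

#' Distribution specification
#'
#' A small serialisable description of a univariate sampling
#' distribution, used by the cohort simulator for ancestral allele
#' frequencies, effect sizes and deleteriousness scores.
#'
#' @param dist one of `"uniform"`, `"beta"`, `"gamma"`, `"exponential"`,
#'   `"lognormal"`, `"fixed"`.
#' @param ... distribution parameters: `min`/`max` (uniform),
#'   `shape1`/`shape2` (beta), `shape`/`rate` (gamma), `rate`
#'   (exponential), `meanlog`/`sdlog` (lognormal), `value` (fixed).
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("uniform", min = 0.05, max = 0.95)
#' dist_spec("exponential", rate = 0.25)
#' @export
dist_spec <- function(dist = c("uniform", "beta", "gamma", "exponential",
                               "lognormal", "fixed"), ...) {
  dist <- match.arg(dist)
  pars <- list(...)
  defaults <- switch(dist,
    uniform     = list(min = 0, max = 1),
    beta        = list(shape1 = 1, shape2 = 1),
    gamma       = list(shape = 1, rate = 1),
    exponential = list(rate = 1),
    lognormal   = list(meanlog = 0, sdlog = 1),
    fixed       = list(value = 1)
  )
  bad <- setdiff(names(pars), names(defaults))
  if (length(bad))
    config_error(sprintf("unknown parameter(s) %s for distribution '%s'",
                         paste(bad, collapse = ", "), dist))
  defaults[names(pars)] <- pars
  structure(c(list(dist = dist), defaults), class = "dist_spec")
}

#' @noRd
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$dist,
    uniform     = runif(n, spec$min, spec$max),
    beta        = rbeta(n, spec$shape1, spec$shape2),
    gamma       = rgamma(n, shape = spec$shape, rate = spec$rate),
    exponential = rexp(n, rate = spec$rate),
    lognormal   = rlnorm(n, spec$meanlog, spec$sdlog),
    fixed       = rep(spec$value, n)
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "dist")]
  cat(sprintf("<dist_spec> %s(%s)\n", x$dist,
              paste(sprintf("%s=%g", names(pars), unlist(pars)),
                    collapse = ", ")))
  invisible(x)
}

# format numbers for TSV output so reruns are byte-identical across
# platforms: fixed significant digits, no scientific notation surprises
fmt_num <- function(x, digits = 10) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}
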