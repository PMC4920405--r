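#' Parameter names required by a model flavour
#'
#' GUTS Proper uses \code{(hb, ke, kk, mn, sd)}; GUTS-SD (delta thresholds)
#' drops \code{sd}; GUTS-IT drops \code{kk}.
#'
#' @param config a \code{\linkS4class{GutsConfig}}.
#' @return character vector of parameter names, in canonical order.
#' @export
paramNames <- function(config) {
  if (config@dist == "delta") c("hb", "ke", "kk", "mn")
  else if (config@model == "it") c("hb", "ke", "mn", "sd")
  else c("hb", "ke", "kk", "mn", "sd")
}

#' Classify a parameter vector for a model flavour
#'
#' A pure classification: never throws on numeric input.  A vector whose
#' length does not match the flavour's arity is \code{"wrong_arity"}; one
#' containing negative, NaN or non-finite values is \code{"improper"};
#' anything else is \code{"proper"}.
#'
#' @param params numeric vector (named or positional in canonical order).
#' @param config a \code{\linkS4class{GutsConfig}}.
#' @return one of \code{"proper"}, \code{"improper"}, \code{"wrong_arity"}.
#' @examples
#' cfg <- gutsConfig()
#' checkParameters(c(0.05, 0.1, 3, 20, 10), cfg)   # "proper"
#' checkParameters(c(0.05, 0.1, 3, 20), cfg)       # "wrong_arity"
#' checkParameters(c(-0.1, 0.1, 3, 20, 10), cfg)   # "improper"
#' @export
checkParameters <- function(params, config) {
  if (length(params) != length(paramNames(config))) return("wrong_arity")
  p <- as.numeric(params)
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0)) return("improper")
  "proper"
}

# order a parameter vector canonically; unnamed vectors are taken positional
.orderParams <- function(params, config) {
  nm <- paramNames(config)
  p <- as.numeric(params)
  if (!is.null(names(params)) && all(nm %in% names(params)))
    p <- p[match(nm, names(params))]
  names(p) <- nm
  p
}
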