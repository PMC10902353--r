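#' Classify annual mean temperature into a manure-MCF climate class
#'
#' Methane conversion factors for manure management depend on how warm the
#' storage environment is. Cities are binned by annual mean temperature
#' into three classes with half-open bins assigned upward:
#' cool `(-Inf, 15)`, temperate `[15, 25)`, warm `[25, Inf)` degrees C.
#' The bin edges follow the three-class structure of IPCC manure MCF
#' tables and are the package's declared convention.
#'
#' @param mean_temp Numeric vector of annual mean temperatures (degrees C),
#'   each finite and within `[-30, 40]`.
#' @return Character vector, one of `"cool"`, `"temperate"`, `"warm"`.
#' @export
#' @examples
#' classify_climate(c(8, 15, 26.3))
classify_climate <- function(mean_temp) {
  if (!is.numeric(mean_temp) || any(!is.finite(mean_temp)))
    stop("mean_temp must be finite numeric", call. = FALSE)
  if (any(mean_temp < -30 | mean_temp > 40))
    stop("mean_temp outside plausible range [-30, 40] degrees C",
         call. = FALSE)
  ifelse(mean_temp < 15, "cool", ifelse(mean_temp < 25, "temperate", "warm"))
}
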