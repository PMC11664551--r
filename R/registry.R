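#' Variable registry for the orchard study
#'
#' The study measures 16 environmental factors per orchard (2 meteorological,
#' 2 topographic, 12 soil) and 12 fruit-quality traits. Short codes
#' (\code{C1}, \code{C2}, \code{T1}, \code{T2}, \code{S1}--\code{S12},
#' \code{Y1}--\code{Y11}, \code{TSS}) are the canonical column names used
#' throughout the package; long names and units live only in this registry.
#'
#' The \code{sense} column records the direction in which each quality trait
#' is considered desirable: \code{"minimize"} for shape index (\code{Y4},
#' rounder fruit) and titratable acid (\code{Y9}, less sour), \code{"maximize"}
#' for the other ten modeled traits, and \code{"none"} for total soluble
#' solids (\code{TSS}), which enters no regression equation.
#'
#' @return A data frame with columns \code{code}, \code{name}, \code{unit},
#'   \code{category} (one of \code{meteorological}, \code{topographic},
#'   \code{soil}, \code{quality}) and \code{sense}.
#' @examples
#' reg <- variable_registry()
#' subset(reg, category == "soil")
#' @export
variable_registry <- function() {
  path <- system.file("extdata", "variable_registry.csv", package = "navelopt",
                      mustWork = TRUE)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(reg$code))
  reg
}

#' Codes of the 16 environmental factors, in canonical order
#' @return Character vector \code{C1, C2, T1, T2, S1, ..., S12}.
#' @export
factor_codes <- function() {
  c("C1", "C2", "T1", "T2", paste0("S", 1:12))
}

#' Codes of the 12 fruit-quality traits, in canonical order
#' @return Character vector \code{Y1, ..., Y11, TSS}.
#' @export
quality_codes <- function() {
  c(paste0("Y", 1:11), "TSS")
}

#' Codes of the 11 modeled quality traits (TSS excluded)
#'
#' TSS is registered with sense \code{"none"}: no environmental factor passes
#' VIP screening for it, so it has no regression equation and takes no part in
#' the optimization stage.
#' @return Character vector \code{Y1, ..., Y11}.
#' @export
modeled_traits <- function() {
  paste0("Y", 1:11)
}

#' Optimization sense of a quality trait
#' @param code trait code.
#' @param registry variable registry (default packaged).
#' @return \code{"maximize"}, \code{"minimize"} or \code{"none"}.
#' @export
trait_sense <- function(code, registry = variable_registry()) {
  i <- match(code, registry$code)
  if (anyNA(i)) stop("unknown variable code: ", paste(code[is.na(i)], collapse = ", "))
  registry$sense[i]
}
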