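#' Flow-unit conversions
#'
#' Airflows appear in three units in practice: the leakage power law and
#' HVAC component data use m3/h, fan levels are quoted in L/s, and the mass
#' balances are integrated in SI (m3/s). These helpers are exact inverses.
#'
#' @param x numeric flow value(s).
#' @return converted numeric of the same length.
#' @name flow-units
NULL

#' @rdname flow-units
#' @export
m3h_to_m3s <- function(x) x / 3600

#' @rdname flow-units
#' @export
m3s_to_m3h <- function(x) x * 3600

#' @rdname flow-units
#' @export
ls_to_m3s <- function(x) x / 1000

#' @rdname flow-units
#' @export
m3s_to_ls <- function(x) x * 1000

#' @rdname flow-units
#' @export
lmin_to_m3s <- function(x) x / 60000

#' HVAC fan-level airflows
#'
#' Nominal total supply airflow for the four fan levels of the modelled
#' vehicles: Xlow, Low, Medium and High correspond to roughly 23, 40, 59 and
#' 86 L/s.
#'
#' @param level one of `"xlow"`, `"low"`, `"medium"`, `"high"`.
#' @return total supply flow in m3/s.
#' @export
#' @examples
#' fan_level_flow("low") * 1000  # 40 L/s
fan_level_flow <- function(level = c("xlow", "low", "medium", "high")) {
  level <- match.arg(level)
  ls_to_m3s(c(xlow = 23, low = 40, medium = 59, high = 86)[[level]])
}
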