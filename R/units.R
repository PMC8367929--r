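#' Convert between concentration units
#'
#' Exact conversion between the units used for methotrexate plasma
#' concentrations: `"mg/mL"` (canonical internal unit), `"ug/mL"`, and
#' `"umol/L"` (via the configured molar mass).
#'
#' @param value Numeric vector of concentrations.
#' @param from,to Units, one of `"mg/mL"`, `"ug/mL"`, `"umol/L"`.
#' @param config An [load_config()] object (used for the molar mass).
#'
#' @return Numeric vector in the target units.
#' @export
#' @examples
#' convert_concentration(0.2, "ug/mL", "umol/L")  # ~0.44 uM
convert_concentration <- function(value, from, to, config = load_config()) {
  mw <- config$drug$molar_mass
  # factors to mg/mL
  to_mgml <- c("mg/mL" = 1, "ug/mL" = 1e-3, "umol/L" = mw * 1e-6)
  norm <- function(u) {
    u <- gsub("µ", "u", u)  # accept micro sign
    u <- c(mg_per_ml = "mg/mL", ug_per_ml = "ug/mL",
           umol_per_L = "umol/L", umol_per_l = "umol/L")[u] %||% u
    if (!u %in% names(to_mgml)) {
      stop("unknown concentration unit: ", u, call. = FALSE)
    }
    u
  }
  value * to_mgml[[norm(from)]] / to_mgml[[norm(to)]]
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
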