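#' Convert between US customary and SI units
#'
#' Historical water-supply records mix US customary units (feet, miles,
#' gallons, million gallons per day) with SI.  Everything internal to this
#' package is SI (metres, days, cubic metres per day, micrograms per litre);
#' this converter is applied once at the configuration boundary.  Conversion
#' factors are the exact legal definitions: 1 ft = 0.3048 m,
#' 1 mi = 1.609344 km, 1 US gal = 0.003785411784 m3.
#'
#' @param value Numeric quantity (vectorised).
#' @param from,to Unit labels.  Supported pairs (either direction):
#'   `ft`/`m`, `mi`/`km`, `gal`/`m3`, `Mgal/day`/`m3/day`.  `from == to` is a
#'   no-op.
#' @param sig_figs Optional integer: round the result to this many significant
#'   figures (as printed values in reports usually are).
#' @return Converted numeric vector.
#' @examples
#' convert_units(0.9e6, "gal", "m3", sig_figs = 2)  # 3400
#' convert_units(70, "mi", "km", sig_figs = 3)      # 113
#' @export
convert_units <- function(value, from, to, sig_figs = NULL) {
  stopifnot(is.numeric(value), is.character(from), is.character(to),
            length(from) == 1L, length(to) == 1L)
  factors <- c(
    "ft->m" = 0.3048,
    "mi->km" = 1.609344,
    "gal->m3" = 0.003785411784,
    "Mgal/day->m3/day" = 3785.411784
  )
  out <- if (identical(from, to)) {
    value
  } else {
    key <- paste0(from, "->", to)
    rkey <- paste0(to, "->", from)
    if (key %in% names(factors)) {
      value * factors[[key]]
    } else if (rkey %in% names(factors)) {
      value / factors[[rkey]]
    } else {
      stop("convert_units: unsupported unit pair '", from, "' -> '", to,
           "' (supported: ft/m, mi/km, gal/m3, Mgal/day/m3/day)")
    }
  }
  if (!is.null(sig_figs)) out <- signif(out, as.integer(sig_figs))
  out
}
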