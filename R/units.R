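#' Unit conversions for oxygen uptake
#'
#' All internal energy quantities are expressed per second
#' (ml O2 per kg per s). Metabolic carts and most published tables report
#' per-minute values; convert at the I/O boundary. The conversion is an exact
#' factor-60 bijection.
#'
#' @param x numeric vector of oxygen uptake values.
#' @return numeric vector in the other unit.
#' @examples
#' vo2_min_to_sec(60)  # 1 ml.kg-1.s-1
#' vo2_sec_to_min(vo2_min_to_sec(47.3)) == 47.3
#' @export
vo2_min_to_sec <- function(x) x / 60

#' @rdname vo2_min_to_sec
#' @export
vo2_sec_to_min <- function(x) x * 60

# 1 mile, as used for track records in the prediction tables
METRES_PER_MILE <- 1609
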