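# ATP economics of pilus assembly: a filament extending at v Angstrom per
# second with a helical rise of h Angstrom per pilin adds v/h pilins per
# second; a rotary cycle spending `atp_per_cycle` ATP to assemble
# `pilins_per_cycle` pilins (2 ATP per 3 pilins in the paired-event rotary
# model) then consumes pilins_per_second * atp_per_cycle / pilins_per_cycle
# ATP per second.

#' Pilin-assembly and ATP-consumption rates from extension kinetics
#'
#' @param extension_rate filament extension speed (Angstrom/s), >= 0.
#' @param helical_rise axial rise per pilin subunit (Angstrom), > 0.
#' @param atp_per_cycle ATP molecules hydrolysed per catalytic cycle
#'   (default 2: one paired binding + hydrolysis event per cycle).
#' @param pilins_per_cycle pilin subunits incorporated per cycle
#'   (default 3: one pilin per platform heterodimer of the trimeric
#'   platform).
#' @return object of class `energetics_result` with `pilins_per_second`
#'   and `atp_per_second`.  Values are exact ratios of the inputs
#'   (`atp_per_second = pilins_per_second * atp_per_cycle /
#'   pilins_per_cycle`).
#' @examples
#' assembly_rates(750, 5)      # Tad pilus: 150 pilins/s, 100 ATP/s
#' assembly_rates(3600, 10)    # T4aP: 360 pilins/s, 240 ATP/s
#' @export
assembly_rates <- function(extension_rate, helical_rise, atp_per_cycle = 2,
                           pilins_per_cycle = 3) {
  if (!is.finite(extension_rate) || extension_rate < 0)
    stopf("extension_rate must be >= 0")
  if (!is.finite(helical_rise) || helical_rise <= 0)
    stopf("helical_rise must be > 0")
  if (atp_per_cycle <= 0 || pilins_per_cycle <= 0)
    stopf("atp_per_cycle and pilins_per_cycle must be > 0")
  pps <- extension_rate / helical_rise
  structure(list(pilins_per_second = pps,
                 atp_per_second = pps * atp_per_cycle / pilins_per_cycle,
                 params = list(extension_rate = extension_rate,
                               helical_rise = helical_rise,
                               atp_per_cycle = atp_per_cycle,
                               pilins_per_cycle = pilins_per_cycle)),
            class = "energetics_result")
}

#' @export
print.energetics_result <- function(x, digits = 6, ...) {
  p <- x$params
  cat(sprintf("<energetics_result> %s A/s extension, %s A rise, %s ATP per %s pilins\n",
              format(p$extension_rate), format(p$helical_rise),
              format(p$atp_per_cycle), format(p$pilins_per_cycle)))
  cat(sprintf("  pilins per second: %s\n", format(x$pilins_per_second, digits = digits)))
  cat(sprintf("  ATP per second:    %s\n", format(x$atp_per_second, digits = digits)))
  invisible(x)
}
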