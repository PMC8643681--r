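# Pure arithmetic of closed-circular DNA topology: Lk = Tw + Wr, the
# intercalator and temperature corrections of the band-counting method,
# and the supercoiling density sigma = Wr / Tw.

#' Describe a circular plasmid
#'
#' A `plasmid_spec` carries the identity of a covalently closed circular DNA
#' molecule: its length in base pairs and the helical repeat (bp per helix
#' turn) that together fix its relaxed twist `Tw = length_bp / helical_repeat`.
#'
#' @param name Text label for the plasmid (e.g. `"pTPTK2"`).
#' @param length_bp Plasmid length in base pairs; must be at least 100.
#' @param helical_repeat Helical repeat in bp per turn; default 10.5, the
#'   B-DNA value under standard conditions.
#'
#' @return An object of class `plasmid_spec`.
#' @examples
#' p <- plasmid_spec("pTPTK2", 5455)
#' twist(p)
#' @export
plasmid_spec <- function(name, length_bp, helical_repeat = 10.5) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(length_bp) || length(length_bp) != 1L ||
      !is.finite(length_bp) || length_bp < 100 ||
      length_bp != round(length_bp)) {
    stop("'length_bp' must be a single integer >= 100", call. = FALSE)
  }
  if (!is.numeric(helical_repeat) || length(helical_repeat) != 1L ||
      !is.finite(helical_repeat) || helical_repeat <= 0) {
    stop("'helical_repeat' must be a single positive number", call. = FALSE)
  }
  structure(
    list(name = name, length_bp = as.numeric(length_bp),
         helical_repeat = helical_repeat),
    class = "plasmid_spec"
  )
}

#' @export
print.plasmid_spec <- function(x, ...) {
  cat(sprintf("<plasmid_spec> %s: %d bp, h = %g bp/turn (Tw = %.2f turns)\n",
              x$name, as.integer(x$length_bp), x$helical_repeat, twist(x)))
  invisible(x)
}

assert_plasmid <- function(plasmid) {
  if (!inherits(plasmid, "plasmid_spec")) {
    stop("expected a 'plasmid_spec' object; see plasmid_spec()", call. = FALSE)
  }
  invisible(plasmid)
}

#' Relaxed twist of a plasmid
#'
#' Twist of the relaxed molecule in helix turns: the plasmid length in base
#' pairs divided by the helical repeat.
#'
#' @param plasmid A [plasmid_spec()].
#' @return Twist in turns (positive real).
#' @examples
#' twist(plasmid_spec("pTPTK2", 5455)) # 519.52
#' @export
twist <- function(plasmid) {
  assert_plasmid(plasmid)
  plasmid$length_bp / plasmid$helical_repeat
}

#' Correction parameters for the band-counting method
#'
#' Houses the physical constants used to translate apparent (gel) writhe into
#' native writhe: the change in helix rotation per degree Celsius per base
#' pair, the 360 degrees/turn convention, the chloroquine unwinding
#' coefficient used by the virtual-gel simulator, and whether whole-supercoil
#' corrections are rounded to the nearest integer.
#'
#' @param temp_coefficient Magnitude of the helix-angle change in degrees per
#'   degree Celsius per base pair; default 0.011.
#' @param degrees_per_turn Degrees in one helix turn; 360 by convention.
#' @param chloroquine_unwinding Unwinding coefficient in turns per
#'   (ug/ml x bp); default calibrated from 19 supercoils introduced at
#'   1.5 ug/ml in a 5455 bp plasmid (see
#'   [calibrate_chloroquine_coefficient()]). Used only by the simulator.
#' @param round_corrections If `TRUE` (default), whole-supercoil corrections
#'   are rounded to the nearest integer, matching how supercoils are counted
#'   on a gel.
#'
#' @return An object of class `correction_parameters`.
#' @export
correction_parameters <- function(temp_coefficient = 0.011,
                                  degrees_per_turn = 360,
                                  chloroquine_unwinding = 19 / (1.5 * 5455),
                                  round_corrections = TRUE) {
  stopifnot(
    is.numeric(temp_coefficient), length(temp_coefficient) == 1L,
    temp_coefficient >= 0,
    is.numeric(degrees_per_turn), length(degrees_per_turn) == 1L,
    degrees_per_turn > 0,
    is.numeric(chloroquine_unwinding), length(chloroquine_unwinding) == 1L,
    chloroquine_unwinding >= 0,
    is.logical(round_corrections), length(round_corrections) == 1L
  )
  structure(
    list(temp_coefficient = temp_coefficient,
         degrees_per_turn = degrees_per_turn,
         chloroquine_unwinding = chloroquine_unwinding,
         round_corrections = round_corrections),
    class = "correction_parameters"
  )
}

assert_params <- function(params) {
  if (!inherits(params, "correction_parameters")) {
    stop("expected a 'correction_parameters' object", call. = FALSE)
  }
  invisible(params)
}

#' Writhe shift introduced by a temperature change
#'
#' DNA twist depends on temperature: cooling tightens the helix, and at
#' constant linking number the extra twist is compensated by negative writhe.
#' The shift in whole supercoils between the growth temperature and the gel
#' temperature is
#' `(t_gel - t_growth) * temp_coefficient * length_bp / degrees_per_turn`,
#' negative when the gel is colder than growth.
#'
#' @param plasmid A [plasmid_spec()].
#' @param t_growth_C Growth temperature in degrees Celsius.
#' @param t_gel_C Electrophoresis temperature in degrees Celsius.
#' @param params A [correction_parameters()]; if `round_corrections` is set
#'   the result is rounded to the nearest whole supercoil.
#'
#' @return Writhe shift in supercoils (real; integer-valued when rounded).
#' @examples
#' p <- plasmid_spec("pTPTK2", 5455)
#' temperature_writhe_shift(p, 85, 24) # -10 supercoils
#' @export
temperature_writhe_shift <- function(plasmid, t_growth_C, t_gel_C,
                                     params = correction_parameters()) {
  assert_plasmid(plasmid)
  assert_params(params)
  stopifnot(is.numeric(t_growth_C), is.numeric(t_gel_C),
            length(t_growth_C) == 1L, length(t_gel_C) == 1L,
            is.finite(t_growth_C), is.finite(t_gel_C))
  dw <- (t_gel_C - t_growth_C) * params$temp_coefficient *
    plasmid$length_bp / params$degrees_per_turn
  if (params$round_corrections) dw <- round(dw)
  dw
}

#' Chloroquine-induced writhe shift from a gel pair
#'
#' The number of positive supercoils introduced by intercalation is read
#' directly from the two first-dimension gels run on the same sample: the
#' major-topoisomer writhe on the chloroquine gel minus the major-topoisomer
#' writhe on the no-chloroquine gel.
#'
#' @param wr_with_chl Major-topoisomer apparent writhe with chloroquine.
#' @param wr_without_chl Major-topoisomer apparent writhe without chloroquine.
#' @return The shift in supercoils (positive for an intercalator).
#' @examples
#' chloroquine_shift_from_gels(14, -5) # +19
#' @export
chloroquine_shift_from_gels <- function(wr_with_chl, wr_without_chl) {
  stopifnot(is.numeric(wr_with_chl), is.numeric(wr_without_chl))
  wr_with_chl - wr_without_chl
}

#' Native writhe from apparent writhe and corrections
#'
#' Removes the chloroquine and temperature contributions from the apparent
#' (gel-read) writhe of the major topoisomer:
#' `Wr_native = wr_apparent - delta_wr_chl - delta_wr_temp`.
#' With the convention that the temperature shift is negative for cooling,
#' subtracting it adds back the supercoils lost to the colder gel.
#'
#' @param wr_apparent Major-topoisomer writhe read from the gel.
#' @param delta_wr_chl Supercoils introduced by chloroquine (positive).
#' @param delta_wr_temp Supercoils introduced by the temperature change
#'   (negative when the gel is colder than growth).
#' @return Native writhe at growth temperature, no intercalator.
#' @examples
#' native_writhe(14, 19, -10)  # +5
#' native_writhe(-8, 19, -10)  # -17
#' @export
native_writhe <- function(wr_apparent, delta_wr_chl, delta_wr_temp) {
  stopifnot(is.numeric(wr_apparent), is.numeric(delta_wr_chl),
            is.numeric(delta_wr_temp))
  wr_apparent - delta_wr_chl - delta_wr_temp
}

#' Supercoiling density
#'
#' The dimensionless superhelical density `sigma = Wr_native / Tw`, negative
#' for underwound (negatively supercoiled) DNA. Summaries report sigma to
#' 4 decimal places; the returned value is full precision.
#'
#' @param wr_native Native writhe in supercoils.
#' @param plasmid A [plasmid_spec()].
#' @return sigma (real, dimensionless).
#' @examples
#' p <- plasmid_spec("pTPTK2", 5455)
#' round(supercoiling_density(5, p), 4)   # +0.0096
#' round(supercoiling_density(-17, p), 4) # -0.0327
#' @export
supercoiling_density <- function(wr_native, plasmid) {
  assert_plasmid(plasmid)
  stopifnot(is.numeric(wr_native))
  wr_native / twist(plasmid)
}

#' Linking number of a plasmid with a given writhe
#'
#' `Lk = Tw + Wr` with twist at its relaxed reference, so the linking
#' difference `Lk - Lk0` equals the writhe.
#'
#' @param plasmid A [plasmid_spec()].
#' @param wr Writhe in supercoils.
#' @return Linking number in turns.
#' @export
linking_number <- function(plasmid, wr) {
  assert_plasmid(plasmid)
  stopifnot(is.numeric(wr))
  twist(plasmid) + wr
}

#' Assemble a supercoiling result with its audit trail
#'
#' Container for the output of the two-gel protocol: the apparent writhe,
#' both corrections, the native writhe, twist and sigma, so every
#' intermediate of the calculation can be audited. Normally produced by
#' [run_two_gel_protocol()].
#'
#' @param plasmid A [plasmid_spec()].
#' @param wr_apparent Major-topoisomer writhe under the counting-gel
#'   conditions.
#' @param delta_wr_chloroquine Supercoils introduced by intercalation.
#' @param delta_wr_temperature Supercoils introduced by the temperature
#'   change.
#' @param details Optional named list of extra audit fields (temperatures,
#'   chloroquine concentration, replicate id, ...).
#'
#' @return An object of class `supercoiling_result` with fields `plasmid`,
#'   `wr_apparent`, `delta_wr_chloroquine`, `delta_wr_temperature`,
#'   `wr_native`, `twist`, `sigma` and `details`.
#' @export
supercoiling_result <- function(plasmid, wr_apparent, delta_wr_chloroquine,
                                delta_wr_temperature, details = list()) {
  assert_plasmid(plasmid)
  wr_nat <- native_writhe(wr_apparent, delta_wr_chloroquine,
                          delta_wr_temperature)
  structure(
    list(plasmid = plasmid,
         wr_apparent = wr_apparent,
         delta_wr_chloroquine = delta_wr_chloroquine,
         delta_wr_temperature = delta_wr_temperature,
         wr_native = wr_nat,
         twist = twist(plasmid),
         sigma = supercoiling_density(wr_nat, plasmid),
         details = details),
    class = "supercoiling_result"
  )
}

#' @export
print.supercoiling_result <- function(x, ...) {
  cat(sprintf("<supercoiling_result> %s (%d bp, Tw = %.2f)\n",
              x$plasmid$name, as.integer(x$plasmid$length_bp), x$twist))
  cat(sprintf("  apparent Wr (gel):        %+g\n", x$wr_apparent))
  cat(sprintf("  - chloroquine shift:      %+g\n", x$delta_wr_chloroquine))
  cat(sprintf("  - temperature shift:      %+g\n", x$delta_wr_temperature))
  cat(sprintf("  native Wr:                %+g\n", x$wr_native))
  cat(sprintf("  sigma = Wr/Tw:            %+.4f\n", x$sigma))
  invisible(x)
}
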