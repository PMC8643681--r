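# Orchestration of the two-gel protocol: paired first-dimension gels with
# and without chloroquine, band counting, corrections, sigma, and replicate
# aggregation.

#' Bundle a two-gel experiment
#'
#' Pairs the two first-dimension ladders measured on the same sample: one
#' without chloroquine (preserving native topology) and one with chloroquine
#' (the counting gel that resolves extreme topoisomers), together with the
#' temperatures and correction parameters.
#'
#' @param plasmid A [plasmid_spec()].
#' @param growth_temp_C Growth temperature in degrees Celsius.
#' @param gel_temp_C Electrophoresis temperature in degrees Celsius.
#' @param ladder_no_chl [band_ladder()] from the no-chloroquine gel; may be
#'   flagged `saturated` when only the front band is visible.
#' @param ladder_with_chl [band_ladder()] from the chloroquine gel.
#' @param chloroquine_dim1_ug_ml Chloroquine concentration of the counting
#'   gel, ug/ml (> 0).
#' @param params A [correction_parameters()].
#'
#' @return An object of class `two_gel_experiment`.
#' @export
two_gel_experiment <- function(plasmid, growth_temp_C, gel_temp_C,
                               ladder_no_chl, ladder_with_chl,
                               chloroquine_dim1_ug_ml = 1.5,
                               params = correction_parameters()) {
  assert_plasmid(plasmid)
  assert_ladder(ladder_no_chl)
  assert_ladder(ladder_with_chl)
  assert_params(params)
  scalar_number(growth_temp_C, "growth_temp_C")
  scalar_number(gel_temp_C, "gel_temp_C")
  scalar_number(chloroquine_dim1_ug_ml, "chloroquine_dim1_ug_ml",
                lower = 0, strict_lower = TRUE)
  structure(
    list(plasmid = plasmid, growth_temp_C = growth_temp_C,
         gel_temp_C = gel_temp_C, ladder_no_chl = ladder_no_chl,
         ladder_with_chl = ladder_with_chl,
         chloroquine_dim1_ug_ml = chloroquine_dim1_ug_ml,
         params = params),
    class = "two_gel_experiment"
  )
}

ladder_major_writhe <- function(ladder, what) {
  idx <- major_topoisomer(ladder)
  wr <- ladder$bands$assigned_writhe[idx]
  if (is.na(wr)) {
    stop(sprintf("%s ladder has no assigned writhes; run assign_writhe()",
                 what), call. = FALSE)
  }
  wr
}

#' Run the two-gel band-counting protocol
#'
#' Computes the full correction chain: the chloroquine shift from the major
#' writhes of the paired gels (or an externally calibrated value when the
#' no-chloroquine gel is saturated), the temperature shift from growth to
#' gel temperature, the native writhe, and the supercoiling density. Every
#' intermediate is retained in the result for audit.
#'
#' When the no-chloroquine lane shows only the saturated front band
#' (extreme supercoiling), the chloroquine shift cannot be read from this
#' sample's gel pair and must be supplied via `delta_wr_chl` (e.g. from a
#' control sample's pair); otherwise an error of class
#' `topogel_front_band_error` is raised.
#'
#' @param exp A [two_gel_experiment()].
#' @param delta_wr_chl Optional externally determined chloroquine shift in
#'   supercoils.
#' @return A [supercoiling_result()].
#' @examples
#' # pTPTK2 worked example: majors -5 (no chloroquine) and +14 (with)
#' p <- plasmid_spec("pTPTK2", 5455)
#' no_chl <- assign_writhe(band_ladder(0:6, c(1, 1, 2, 4, 6, 9, 5)),
#'                         reference_writhe = 0, sign_direction = -1,
#'                         reference_index = 1)
#' with_chl <- assign_writhe(band_ladder(0:15, c(1, rep(2, 13), 9, 3)),
#'                           reference_writhe = 0, sign_direction = 1,
#'                           reference_index = 1)
#' res <- run_two_gel_protocol(
#'   two_gel_experiment(p, 85, 24, no_chl, with_chl))
#' res # sigma = +0.0096
#' @export
run_two_gel_protocol <- function(exp, delta_wr_chl = NULL) {
  if (!inherits(exp, "two_gel_experiment")) {
    stop("expected a 'two_gel_experiment' object", call. = FALSE)
  }
  wr_with <- ladder_major_writhe(exp$ladder_with_chl, "with-chloroquine")
  if (is.null(delta_wr_chl)) {
    if (exp$ladder_no_chl$saturated) {
      stop(structure(
        class = c("topogel_front_band_error", "error", "condition"),
        list(message = paste(
          "extreme supercoiling: the no-chloroquine gel shows only a",
          "saturated front band, so the chloroquine shift cannot be counted;",
          "supply 'delta_wr_chl' calibrated from a resolvable sample"),
          call = NULL)))
    }
    wr_no <- ladder_major_writhe(exp$ladder_no_chl, "no-chloroquine")
    delta_wr_chl <- chloroquine_shift_from_gels(wr_with, wr_no)
  }
  delta_wr_temp <- temperature_writhe_shift(exp$plasmid, exp$growth_temp_C,
                                            exp$gel_temp_C, exp$params)
  supercoiling_result(
    exp$plasmid,
    wr_apparent = wr_with,
    delta_wr_chloroquine = delta_wr_chl,
    delta_wr_temperature = delta_wr_temp,
    details = list(growth_temp_C = exp$growth_temp_C,
                   gel_temp_C = exp$gel_temp_C,
                   chloroquine_dim1_ug_ml = exp$chloroquine_dim1_ug_ml)
  )
}

#' Aggregate replicate supercoiling measurements
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' sigma across independent gel experiments on the same plasmid.
#'
#' @param results List of [supercoiling_result()] objects.
#' @return A list with `mean_sigma`, `sd_sigma` (`NA` for a single
#'   replicate) and `n`.
#' @export
aggregate_replicates <- function(results) {
  if (!is.list(results) || length(results) < 1L ||
      !all(vapply(results, inherits, logical(1), "supercoiling_result"))) {
    stop("expected a non-empty list of 'supercoiling_result' objects",
         call. = FALSE)
  }
  ids <- vapply(results, function(r)
    paste(r$plasmid$name, r$plasmid$length_bp), character(1))
  if (length(unique(ids)) > 1L) {
    stop("replicates mix different plasmids: ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  }
  sig <- vapply(results, function(r) r$sigma, numeric(1))
  list(mean_sigma = mean(sig),
       sd_sigma = if (length(sig) > 1L) stats::sd(sig) else NA_real_,
       n = length(sig))
}

#' Compare supercoiling densities between strains
#'
#' Reports both quantities used to express a change in supercoiling: the
#' magnitude ratio `|sigma_test| / |sigma_control|` and the signed
#' difference `sigma_test - sigma_control`. Both are surfaced because a
#' phrase like "n-fold increase" maps onto either depending on convention.
#'
#' @param test [supercoiling_result()] (or a bare sigma value) for the test
#'   strain.
#' @param control [supercoiling_result()] (or a bare sigma value) for the
#'   control strain.
#' @return A list with `ratio` and `delta_sigma`. A zero control sigma
#'   yields an infinite ratio with a warning.
#' @examples
#' fold_change_sigma(-0.0327, 0.0077) # ratio 4.25, delta -0.0404
#' @export
fold_change_sigma <- function(test, control) {
  sig <- function(x) {
    if (inherits(x, "supercoiling_result")) x$sigma
    else scalar_number(x, "sigma")
  }
  s_t <- sig(test)
  s_c <- sig(control)
  if (s_c == 0) {
    warning("control sigma is zero; ratio reported as infinite",
            call. = FALSE)
    ratio <- Inf
  } else {
    ratio <- abs(s_t) / abs(s_c)
  }
  list(ratio = ratio, delta_sigma = s_t - s_c)
}
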