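# Simulator -> analyzer round trip: plant a topoisomer population of known
# topology, render the two-gel protocol, re-analyze the virtual gels, and
# compare the recovered native writhe against ground truth.

# Analyze one rendered 1D lane against the simulator's ground truth register:
# detect bands, match them to the predicted migration positions of the
# population's effective writhes, and assign writhe by band counting anchored
# on the matched reference band.
analyze_virtual_lane <- function(dist, gel, growth_temp_C, params) {
  eff <- effective_writhe(dist$entries$writhe_native, dist$plasmid, gel,
                          growth_temp_C, params, dimension = 1)
  if (any(abs(eff) >= gel$mobility_saturation_wr)) {
    return(list(ok = FALSE, reason = "saturated"))
  }
  if (any(eff > 0) && any(eff < 0)) {
    return(list(ok = FALSE, reason = "folded"))
  }
  profile <- render_gel(dist, gel, growth_temp_C, params, mode = "1D")
  spacing <- gel$max_position / gel$mobility_saturation_wr
  single_height <- 1 / (sqrt(2 * pi) * gel$band_width)
  ladder <- detect_bands(profile,
                         min_prominence = 0.25 * single_height,
                         min_separation = 0.5 * spacing)
  if (nrow(ladder$bands) == 0L) {
    return(list(ok = FALSE, reason = "no-bands"))
  }
  predicted <- migrate(eff, gel)
  matched <- eff[vapply(ladder$bands$position,
                        function(p) which.min(abs(predicted - p)),
                        integer(1))]
  steps <- diff(matched)
  if (length(steps) > 0L && !(all(steps == 1) || all(steps == -1))) {
    return(list(ok = FALSE, reason = "gap"))
  }
  direction <- if (length(steps) > 0L) steps[1] else
    if (matched[1] >= 0) 1 else -1
  ladder <- assign_writhe(ladder, reference_writhe = matched[1],
                          sign_direction = direction, reference_index = 1L)
  list(ok = TRUE, ladder = ladder, eff = eff)
}

#' Round-trip writhe recovery through the virtual two-gel protocol
#'
#' Samples a topoisomer population with a planted native writhe
#' distribution, renders the paired first-dimension gels (without
#' chloroquine and with the counting-gel concentration), detects and counts
#' bands, runs the correction chain, and reports whether the recovered
#' native writhe matches the planted major topoisomer.
#'
#' The ladder register is anchored on simulator ground truth (each detected
#' band is matched to the predicted position of its known effective writhe),
#' mirroring the experimental requirement for an explicit external
#' reference; the sign direction plays the role of the 2D arc inspection. A
#' lane is unresolvable when any species reaches the saturated front band,
#' or when the effective writhe of the population spans both signs so the
#' ladder folds back on itself in one dimension.
#'
#' @param plasmid A [plasmid_spec()].
#' @param center_writhe Planted centre of the native writhe distribution.
#' @param spread Distribution standard deviation in supercoils.
#' @param n_molecules Population size.
#' @param growth_temp_C,gel_temp_C Growth and electrophoresis temperatures.
#' @param chl_counting_ug_ml Chloroquine concentration of the counting gel.
#' @param params A [correction_parameters()].
#' @param mobility_saturation_wr,band_width Virtual gel mobility settings,
#'   see [gel_conditions()].
#' @param seed Integer seed for the population draw.
#'
#' @return A list: `resolvable` (logical), and when resolvable also
#'   `result` (the [supercoiling_result()]), `wr_native`, `sigma`,
#'   `true_major_writhe` (planted ground truth) and `recovered`
#'   (exact agreement flag); otherwise `reason`.
#' @examples
#' p <- plasmid_spec("pTPTK2", 5455)
#' rt <- two_gel_round_trip(p, center_writhe = -17, spread = 1.5, seed = 7)
#' rt$recovered
#' @export
two_gel_round_trip <- function(plasmid, center_writhe, spread = 1.5,
                               n_molecules = 5000, growth_temp_C = 85,
                               gel_temp_C = 24, chl_counting_ug_ml = 1.5,
                               params = correction_parameters(),
                               mobility_saturation_wr = 30,
                               band_width = 0.6, seed = 1L) {
  assert_plasmid(plasmid)
  dist <- sample_topoisomers(plasmid, center_writhe, spread, n_molecules,
                             seed = seed)
  i_major <- which.max(dist$entries$abundance)
  true_major <- dist$entries$writhe_native[i_major]

  gel_no <- gel_conditions(temperature_C = gel_temp_C,
                           chloroquine_dim1_ug_ml = 0,
                           mobility_saturation_wr = mobility_saturation_wr,
                           band_width = band_width, seed = seed)
  gel_chl <- gel_conditions(temperature_C = gel_temp_C,
                            chloroquine_dim1_ug_ml = chl_counting_ug_ml,
                            mobility_saturation_wr = mobility_saturation_wr,
                            band_width = band_width, seed = seed)

  lane_chl <- analyze_virtual_lane(dist, gel_chl, growth_temp_C, params)
  if (!lane_chl$ok) {
    return(list(resolvable = FALSE,
                reason = paste0("counting gel: ", lane_chl$reason),
                true_major_writhe = true_major))
  }
  lane_no <- analyze_virtual_lane(dist, gel_no, growth_temp_C, params)

  if (lane_no$ok) {
    ladder_no <- lane_no$ladder
    delta_chl <- NULL
  } else {
    # front band (or folded lane): fall back on the calibrated shift, as a
    # real experiment would use a resolvable control sample's gel pair
    ladder_no <- band_ladder(gel_no$max_position, 1, saturated = TRUE)
    dchl <- params$chloroquine_unwinding * chl_counting_ug_ml *
      plasmid$length_bp
    delta_chl <- if (params$round_corrections) round(dchl) else dchl
  }

  exp <- two_gel_experiment(plasmid, growth_temp_C, gel_temp_C,
                            ladder_no_chl = ladder_no,
                            ladder_with_chl = lane_chl$ladder,
                            chloroquine_dim1_ug_ml = chl_counting_ug_ml,
                            params = params)
  result <- run_two_gel_protocol(exp, delta_wr_chl = delta_chl)
  list(resolvable = TRUE,
       result = result,
       wr_native = result$wr_native,
       sigma = result$sigma,
       true_major_writhe = true_major,
       recovered = result$wr_native == true_major)
}
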