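# Virtual gel electrophoresis: topoisomer populations of known topology are
# rendered as 1D intensity profiles or 2D band tables so the band-counting
# pipeline can be validated by parameter recovery.

#' Gel running conditions for the virtual gel
#'
#' @param temperature_C Electrophoresis temperature in degrees Celsius
#'   (default 24).
#' @param chloroquine_dim1_ug_ml Chloroquine concentration in the
#'   first-dimension gel and buffer, ug/ml (default 0).
#' @param chloroquine_dim2_ug_ml Chloroquine concentration in the
#'   second-dimension run, ug/ml (default 7.5).
#' @param mobility_saturation_wr Effective writhe magnitude beyond which
#'   topoisomers co-migrate as a single front band (default 30 supercoils).
#' @param band_width Gaussian band standard deviation in position units
#'   (default 0.6).
#' @param noise_sd Standard deviation of additive Gaussian noise on rendered
#'   intensity profiles (default 0 = noise-free).
#' @param max_position Migration distance of the front band in position
#'   units (default 100).
#' @param seed Integer seed controlling all randomness in rendering.
#'
#' @return An object of class `gel_conditions`.
#' @export
gel_conditions <- function(temperature_C = 24,
                           chloroquine_dim1_ug_ml = 0,
                           chloroquine_dim2_ug_ml = 7.5,
                           mobility_saturation_wr = 30,
                           band_width = 0.6,
                           noise_sd = 0,
                           max_position = 100,
                           seed = 1L) {
  scalar_number(temperature_C, "temperature_C")
  scalar_number(chloroquine_dim1_ug_ml, "chloroquine_dim1_ug_ml", lower = 0)
  scalar_number(chloroquine_dim2_ug_ml, "chloroquine_dim2_ug_ml", lower = 0)
  scalar_number(mobility_saturation_wr, "mobility_saturation_wr",
                lower = 0, strict_lower = TRUE)
  scalar_number(band_width, "band_width", lower = 0, strict_lower = TRUE)
  scalar_number(noise_sd, "noise_sd", lower = 0)
  scalar_number(max_position, "max_position", lower = 0, strict_lower = TRUE)
  structure(
    list(temperature_C = temperature_C,
         chloroquine_dim1_ug_ml = chloroquine_dim1_ug_ml,
         chloroquine_dim2_ug_ml = chloroquine_dim2_ug_ml,
         mobility_saturation_wr = mobility_saturation_wr,
         band_width = band_width,
         noise_sd = noise_sd,
         max_position = max_position,
         seed = as.integer(seed)),
    class = "gel_conditions"
  )
}

assert_gel <- function(gel) {
  if (!inherits(gel, "gel_conditions")) {
    stop("expected a 'gel_conditions' object", call. = FALSE)
  }
  invisible(gel)
}

#' Sample a topoisomer population
#'
#' Draws a population of `n_molecules` closed-circular molecules whose
#' integer native writhe follows a Gaussian density centred at
#' `center_writhe` with standard deviation `spread`, multinomially sampled.
#' Deterministic given `seed`.
#'
#' @param plasmid A [plasmid_spec()].
#' @param center_writhe Centre of the writhe distribution (real).
#' @param spread Standard deviation of the distribution in supercoils
#'   (positive).
#' @param n_molecules Number of molecules to sample (>= 1).
#' @param seed Integer seed.
#' @param nicked_fraction Fraction of the total population that is nicked
#'   (open circular), in `[0, 1)`; nicked molecules carry no supercoils and
#'   migrate at position 0.
#'
#' @return An object of class `topoisomer_distribution` with fields
#'   `plasmid`, `entries` (data frame `writhe_native`, `abundance`) and
#'   `nicked_fraction`.
#' @examples
#' p <- plasmid_spec("pTPTK2", 5455)
#' d <- sample_topoisomers(p, center_writhe = -17, spread = 1.5,
#'                         n_molecules = 5000, seed = 42)
#' head(d$entries)
#' @export
sample_topoisomers <- function(plasmid, center_writhe, spread, n_molecules,
                               seed = 1L, nicked_fraction = 0) {
  assert_plasmid(plasmid)
  scalar_number(center_writhe, "center_writhe")
  scalar_number(spread, "spread", lower = 0, strict_lower = TRUE)
  if (!is.numeric(n_molecules) || length(n_molecules) != 1L ||
      n_molecules < 1 || n_molecules != round(n_molecules)) {
    stop("'n_molecules' must be a single integer >= 1", call. = FALSE)
  }
  scalar_number(nicked_fraction, "nicked_fraction", lower = 0, upper = 1)
  grid <- seq(floor(center_writhe - 6 * spread - 1),
              ceiling(center_writhe + 6 * spread + 1))
  p <- stats::dnorm(grid, mean = center_writhe, sd = spread)
  if (sum(p) <= 0) { # pathological spread; put all mass on nearest integer
    p <- as.numeric(grid == round(center_writhe))
  }
  counts <- with_seed(seed,
    stats::rmultinom(1, size = n_molecules, prob = p / sum(p))[, 1])
  keep <- counts > 0
  structure(
    list(plasmid = plasmid,
         entries = data.frame(writhe_native = grid[keep],
                              abundance = as.numeric(counts[keep])),
         nicked_fraction = nicked_fraction),
    class = "topoisomer_distribution"
  )
}

#' Calibrate the chloroquine unwinding coefficient
#'
#' One-point calibration of the linear unwinding model: the coefficient `u`
#' in turns per (ug/ml x bp) such that a concentration `c` shifts the
#' apparent writhe of an `N` bp plasmid by `u * c * N` supercoils. The
#' default [correction_parameters()] coefficient is fixed from 19 supercoils
#' introduced at 1.5 ug/ml in a 5455 bp plasmid.
#'
#' @param supercoils_introduced Observed writhe shift in supercoils.
#' @param concentration_ug_ml Chloroquine concentration, ug/ml (> 0).
#' @param plasmid A [plasmid_spec()].
#' @return The coefficient `u` (turns per (ug/ml x bp)).
#' @examples
#' calibrate_chloroquine_coefficient(19, 1.5, plasmid_spec("pTPTK2", 5455))
#' @export
calibrate_chloroquine_coefficient <- function(supercoils_introduced,
                                              concentration_ug_ml, plasmid) {
  assert_plasmid(plasmid)
  scalar_number(supercoils_introduced, "supercoils_introduced")
  scalar_number(concentration_ug_ml, "concentration_ug_ml",
                lower = 0, strict_lower = TRUE)
  supercoils_introduced / (concentration_ug_ml * plasmid$length_bp)
}

#' Effective writhe of a topoisomer under gel conditions
#'
#' The writhe a topoisomer displays on the gel: its native writhe plus the
#' temperature shift (growth to gel temperature) plus the chloroquine shift
#' `u * c * N` for the chloroquine concentration of the requested gel
#' dimension. With `round_corrections` both corrections are whole
#' supercoils, so integer native writhe maps to integer effective writhe.
#'
#' @param writhe_native Native writhe (vectorised).
#' @param plasmid A [plasmid_spec()].
#' @param gel A [gel_conditions()].
#' @param growth_temp_C Growth temperature in degrees Celsius.
#' @param params A [correction_parameters()].
#' @param dimension Gel dimension, 1 or 2, selecting the chloroquine
#'   concentration.
#' @return Effective writhe (same length as `writhe_native`).
#' @export
effective_writhe <- function(writhe_native, plasmid, gel, growth_temp_C = 85,
                             params = correction_parameters(),
                             dimension = 1) {
  assert_plasmid(plasmid)
  assert_gel(gel)
  assert_params(params)
  stopifnot(is.numeric(writhe_native), dimension %in% c(1, 2))
  conc <- if (dimension == 1) gel$chloroquine_dim1_ug_ml else
    gel$chloroquine_dim2_ug_ml
  dw_temp <- temperature_writhe_shift(plasmid, growth_temp_C,
                                      gel$temperature_C, params)
  dw_chl <- params$chloroquine_unwinding * conc * plasmid$length_bp
  if (params$round_corrections) dw_chl <- round(dw_chl)
  writhe_native + dw_temp + dw_chl
}

#' Migration position of a topoisomer
#'
#' Saturating piecewise-linear mobility: the migration distance grows
#' linearly with the magnitude of the effective writhe up to the saturation
#' writhe `S = mobility_saturation_wr`, beyond which all topoisomers
#' co-migrate at `max_position` (the front band). Relaxed and nicked species
#' sit at position 0.
#'
#' @param wr_eff Effective writhe (vectorised).
#' @param gel A [gel_conditions()].
#' @return Migration position in `[0, max_position]`.
#' @export
migrate <- function(wr_eff, gel) {
  assert_gel(gel)
  stopifnot(is.numeric(wr_eff))
  gel$max_position * pmin(abs(wr_eff), gel$mobility_saturation_wr) /
    gel$mobility_saturation_wr
}

#' Render a virtual gel
#'
#' In `"1D"` mode returns an intensity profile: a sum of Gaussian bands
#' (standard deviation `band_width`, area proportional to abundance) at the
#' first-dimension migration positions, plus seeded Gaussian noise
#' (`noise_sd`). The position axis extends `8 * band_width` beyond
#' `[0, max_position]` so no band mass is truncated. In `"2D"` mode returns
#' one row per species with its first- and second-dimension coordinates:
#' species with identical first-dimension mobility but opposite writhe sign
#' separate in the second dimension (the two arcs).
#'
#' @param dist A [sample_topoisomers()] distribution.
#' @param gel A [gel_conditions()].
#' @param growth_temp_C Growth temperature in degrees Celsius.
#' @param params A [correction_parameters()].
#' @param mode `"1D"` or `"2D"`.
#' @param n_points Number of samples along the 1D position axis.
#'
#' @return For `"1D"`, a data frame with columns `position`, `intensity`.
#'   For `"2D"`, a data frame with columns `dimension1_position`,
#'   `dimension2_position`, `intensity`, `true_writhe` (ground truth; `NA`
#'   for the nicked species).
#' @export
render_gel <- function(dist, gel, growth_temp_C = 85,
                       params = correction_parameters(),
                       mode = c("1D", "2D"), n_points = 2001) {
  if (!inherits(dist, "topoisomer_distribution")) {
    stop("expected a 'topoisomer_distribution' object", call. = FALSE)
  }
  assert_gel(gel)
  assert_params(params)
  mode <- match.arg(mode)
  if (nrow(dist$entries) == 0L) {
    stop("empty topoisomer distribution", call. = FALSE)
  }
  plasmid <- dist$plasmid
  ab <- dist$entries$abundance
  wr <- dist$entries$writhe_native
  total_closed <- sum(ab)
  nicked_ab <- if (dist$nicked_fraction > 0) {
    total_closed * dist$nicked_fraction / (1 - dist$nicked_fraction)
  } else 0

  eff1 <- effective_writhe(wr, plasmid, gel, growth_temp_C, params,
                           dimension = 1)
  x <- migrate(eff1, gel)

  if (mode == "2D") {
    eff2 <- effective_writhe(wr, plasmid, gel, growth_temp_C, params,
                             dimension = 2)
    y <- migrate(eff2, gel)
    out <- data.frame(dimension1_position = x, dimension2_position = y,
                      intensity = ab, true_writhe = wr)
    if (nicked_ab > 0) {
      out <- rbind(out, data.frame(dimension1_position = 0,
                                   dimension2_position = 0,
                                   intensity = nicked_ab,
                                   true_writhe = NA_real_))
    }
    return(out[order(out$dimension1_position, out$dimension2_position), ,
               drop = FALSE])
  }

  pad <- 8 * gel$band_width
  pos <- seq(-pad, gel$max_position + pad, length.out = n_points)
  centers <- x
  areas <- ab
  if (nicked_ab > 0) {
    centers <- c(0, centers)
    areas <- c(nicked_ab, areas)
  }
  intensity <- rep(0, n_points)
  for (i in seq_along(centers)) {
    intensity <- intensity +
      areas[i] * stats::dnorm(pos, mean = centers[i], sd = gel$band_width)
  }
  if (gel$noise_sd > 0) {
    intensity <- intensity +
      with_seed(gel$seed, stats::rnorm(n_points, sd = gel$noise_sd))
  }
  data.frame(position = pos, intensity = intensity)
}
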