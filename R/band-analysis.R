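# Band detection and writhe assignment for 1D topoisomer ladders: the
# data-level inverse of the virtual gel.

#' Construct a band ladder
#'
#' An ordered set of topoisomer bands from one gel dimension: positions
#' (strictly increasing along the migration axis), intensities, and
#' optionally assigned integer writhes that form a consecutive sequence.
#'
#' @param position Strictly increasing band positions.
#' @param intensity Positive band intensities (height above local baseline).
#' @param assigned_writhe Optional integer writhe per band.
#' @param reference_index Optional index of the band of known writhe.
#' @param sign_direction Optional `+1` or `-1`: the direction in which
#'   writhe changes with increasing migration.
#' @param saturated Logical; `TRUE` when the lane shows only a saturated
#'   front band so individual topoisomers cannot be counted.
#'
#' @return An object of class `band_ladder`.
#' @export
band_ladder <- function(position, intensity, assigned_writhe = NULL,
                        reference_index = NULL, sign_direction = NULL,
                        saturated = FALSE) {
  stopifnot(is.numeric(position), is.numeric(intensity),
            length(position) == length(intensity))
  if (length(position) > 1L && any(diff(position) <= 0)) {
    stop("band positions must be strictly increasing", call. = FALSE)
  }
  if (length(intensity) > 0L && any(intensity <= 0)) {
    stop("band intensities must be positive", call. = FALSE)
  }
  if (!is.null(assigned_writhe)) {
    stopifnot(length(assigned_writhe) == length(position))
    d <- diff(assigned_writhe)
    if (length(d) > 0L && !(all(d == 1) || all(d == -1))) {
      stop("assigned writhes must form a consecutive integer sequence",
           call. = FALSE)
    }
  }
  if (!is.null(reference_index)) {
    stopifnot(length(reference_index) == 1L,
              reference_index >= 1, reference_index <= length(position))
  }
  if (!is.null(sign_direction)) {
    stopifnot(sign_direction %in% c(-1, 1))
  }
  structure(
    list(bands = data.frame(position = position, intensity = intensity,
                            assigned_writhe = if (is.null(assigned_writhe))
                              rep(NA_integer_, length(position)) else
                                as.integer(assigned_writhe)),
         reference_index = reference_index,
         sign_direction = sign_direction,
         saturated = isTRUE(saturated)),
    class = "band_ladder"
  )
}

#' @export
print.band_ladder <- function(x, ...) {
  cat(sprintf("<band_ladder> %d band(s)%s\n", nrow(x$bands),
              if (x$saturated) " [saturated front band]" else ""))
  if (!is.null(x$reference_index)) {
    cat(sprintf("  reference band: index %d\n", x$reference_index))
  }
  print(utils::head(x$bands, 10))
  if (nrow(x$bands) > 10) cat(sprintf("  ... %d more\n", nrow(x$bands) - 10))
  invisible(x)
}

assert_ladder <- function(ladder) {
  if (!inherits(ladder, "band_ladder")) {
    stop("expected a 'band_ladder' object", call. = FALSE)
  }
  invisible(ladder)
}

# Prominence of local maxima: height above the higher of the two minima
# separating the peak from higher terrain (or the profile edge).
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left_min <- h
    i <- p - 1L
    m <- h
    while (i >= 1L && y[i] <= h) {
      m <- min(m, y[i])
      i <- i - 1L
    }
    left_min <- m
    right_min <- h
    i <- p + 1L
    m <- h
    n <- length(y)
    while (i <= n && y[i] <= h) {
      m <- min(m, y[i])
      i <- i + 1L
    }
    right_min <- m
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect bands in a 1D intensity profile
#'
#' Finds local maxima with prominence at least `min_prominence`, then
#' enforces a minimum pairwise separation by greedily keeping the most
#' prominent peak of any conflicting pair (two planted bands closer than
#' `min_separation` are reported as one). Band intensity is the peak
#' prominence, i.e. its height above the local baseline.
#'
#' @param profile Data frame with numeric columns `position` (strictly
#'   increasing) and `intensity`, as written by [render_gel()] in 1D mode.
#' @param min_prominence Minimum peak prominence (intensity units).
#' @param min_separation Minimum separation between reported bands
#'   (position units).
#'
#' @return A [band_ladder()]; empty (0 bands) for a flat profile.
#' @export
detect_bands <- function(profile, min_prominence, min_separation = 0) {
  stopifnot(is.data.frame(profile),
            all(c("position", "intensity") %in% names(profile)))
  if (nrow(profile) < 3L) {
    stop("profile must contain at least 3 points", call. = FALSE)
  }
  pos <- profile$position
  y <- profile$intensity
  if (any(diff(pos) <= 0)) {
    stop("profile position axis must be strictly increasing", call. = FALSE)
  }
  scalar_number(min_prominence, "min_prominence", lower = 0)
  scalar_number(min_separation, "min_separation", lower = 0)

  n <- length(y)
  # local maxima; plateau maxima report their first point
  cand <- which(vapply(2:(n - 1L), function(i) {
    y[i] > y[i - 1L] && y[i] >= y[i + 1L]
  }, logical(1))) + 1L
  if (length(cand) == 0L) {
    return(band_ladder(numeric(0), numeric(0)))
  }
  prom <- peak_prominences(y, cand)
  keep <- prom >= min_prominence & prom > 0
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0L) {
    return(band_ladder(numeric(0), numeric(0)))
  }
  # greedy non-maximum suppression by prominence
  ord <- order(prom, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(pos[cand[i]] - pos[cand[kept]]) >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  kept <- kept[order(pos[cand[kept]])]
  band_ladder(pos[cand[kept]], prom[kept])
}

#' Identify the major topoisomer
#'
#' Returns the index of the maximum-intensity band. Exact intensity ties are
#' broken toward the band nearer the reference (the slower-migrating band
#' when no reference is set), with a warning.
#'
#' @param ladder A [band_ladder()] with at least one band.
#' @return Integer band index.
#' @export
major_topoisomer <- function(ladder) {
  assert_ladder(ladder)
  if (nrow(ladder$bands) == 0L) {
    stop("cannot identify a major topoisomer in an empty ladder",
         call. = FALSE)
  }
  int <- ladder$bands$intensity
  top <- which(int == max(int))
  if (length(top) > 1L) {
    warning("intensity tie for the major topoisomer; ",
            "choosing the band nearer the reference", call. = FALSE)
    ref <- if (is.null(ladder$reference_index)) 1L else ladder$reference_index
    top <- top[which.min(abs(top - ref))]
  }
  top
}

#' Assign integer writhe by band counting
#'
#' Formalises counting bands from a reference of known writhe: band `i`
#' receives `reference_writhe + sign_direction * (i - reference_index)`,
#' where indices follow the migration axis. Writhes are consecutive
#' integers along the ladder.
#'
#' @param ladder A [band_ladder()].
#' @param reference_writhe Known writhe of the reference band.
#' @param sign_direction `+1` if writhe increases with migration distance,
#'   `-1` otherwise (determined from the 2D arc the population occupies).
#' @param reference_index Index of the reference band; defaults to the
#'   ladder's stored `reference_index`.
#'
#' @return The ladder with `assigned_writhe` filled in and the reference
#'   recorded.
#' @export
assign_writhe <- function(ladder, reference_writhe, sign_direction,
                          reference_index = ladder$reference_index) {
  assert_ladder(ladder)
  if (is.null(reference_index)) {
    stop("no reference band: supply 'reference_index' or set it on the ladder",
         call. = FALSE)
  }
  stopifnot(reference_index >= 1, reference_index <= nrow(ladder$bands),
            sign_direction %in% c(-1, 1),
            reference_writhe == round(reference_writhe))
  idx <- seq_len(nrow(ladder$bands))
  ladder$bands$assigned_writhe <-
    as.integer(reference_writhe + sign_direction * (idx - reference_index))
  ladder$reference_index <- as.integer(reference_index)
  ladder$sign_direction <- sign_direction
  ladder
}
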