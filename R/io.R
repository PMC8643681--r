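# Plain-text interchange: TSV profiles, band tables and ladders, DE tables
# with a column alias map, and JSON reports.

#' Read / write a 1D intensity profile
#'
#' Two-column TSV (`position`, `intensity`) with a header.
#'
#' @param file Path to the TSV file.
#' @return `read_profile()` returns a data frame suitable for
#'   [detect_bands()].
#' @export
read_profile <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("position", "intensity") %in% names(df))) {
    stop("profile TSV must have columns 'position' and 'intensity'",
         call. = FALSE)
  }
  df
}

#' @rdname read_profile
#' @param profile Data frame with columns `position`, `intensity`.
#' @export
write_profile <- function(profile, file) {
  utils::write.table(profile[, c("position", "intensity")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a 2D band table or an annotated ladder as TSV
#'
#' For a 2D [render_gel()] table the columns are `dimension1_position`,
#' `dimension2_position`, `intensity` and the ground-truth `true_writhe`.
#' For a [band_ladder()] the columns are `position`, `intensity`,
#' `assigned_writhe` and `is_major`.
#'
#' @param x A 2D band table data frame or a `band_ladder`.
#' @param file Output path.
#' @export
write_band_table <- function(x, file) {
  if (inherits(x, "band_ladder")) {
    df <- x$bands
    df$is_major <- FALSE
    if (nrow(df) > 0L) df$is_major[major_topoisomer(x)] <- TRUE
  } else {
    df <- x
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_band_table
#' @export
read_band_table <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

# canonical name -> accepted aliases (matched case-insensitively)
DE_COLUMN_ALIASES <- list(
  gene_id = c("gene_id", "gene", "geneid", "id", "gene_name", "row.names"),
  log2_fold_change = c("log2_fold_change", "log2foldchange", "log2fc",
                       "lfc", "logfc"),
  p_adjusted = c("p_adjusted", "padj", "adj_p_val", "adj.p.val", "qvalue",
                 "fdr"),
  mean_expression = c("mean_expression", "basemean", "base_mean",
                      "aveexpr", "mean")
)

#' Read a per-gene differential-expression table
#'
#' Reads a delimited table of per-gene statistics as produced by standard
#' DE packages and maps the columns onto the package's canonical names
#' (`gene_id`, `log2_fold_change`, `p_adjusted`, `mean_expression`).
#' Column names are matched case-insensitively against a documented alias
#' map (e.g. `log2FoldChange`, `padj`, `baseMean`), so externally produced
#' tables load unchanged.
#'
#' @param file Path to a TSV/CSV table with a header.
#' @param sep Field separator (default tab).
#' @return Data frame with the canonical columns (plus any extra columns,
#'   untouched), ready for [filter_degs()].
#' @export
read_de_table <- function(file, sep = "\t") {
  df <- utils::read.delim(file, sep = sep, stringsAsFactors = FALSE)
  lower <- tolower(names(df))
  for (canonical in names(DE_COLUMN_ALIASES)) {
    if (canonical %in% names(df)) next
    hit <- which(lower %in% DE_COLUMN_ALIASES[[canonical]])
    if (length(hit) >= 1L) names(df)[hit[1]] <- canonical
  }
  need <- c("gene_id", "log2_fold_change", "p_adjusted")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("DE table lacks required column(s): ",
         paste(missing, collapse = ", "),
         " (accepted aliases are case-insensitive, e.g. log2FoldChange, padj)",
         call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicated gene ids in DE table", call. = FALSE)
  }
  df
}

#' Write a supercoiling result as a JSON report
#'
#' Serialises the full audit trail of a [supercoiling_result()] (or the
#' output of [aggregate_replicates()]) to JSON.
#'
#' @param result A `supercoiling_result` or a list.
#' @param file Output path.
#' @export
write_sigma_report <- function(result, file) {
  x <- if (inherits(result, "supercoiling_result")) {
    list(plasmid = result$plasmid$name,
         length_bp = result$plasmid$length_bp,
         helical_repeat = result$plasmid$helical_repeat,
         twist = result$twist,
         wr_apparent = result$wr_apparent,
         delta_wr_chloroquine = result$delta_wr_chloroquine,
         delta_wr_temperature = result$delta_wr_temperature,
         wr_native = result$wr_native,
         sigma = result$sigma,
         sigma_4dp = round(result$sigma, 4),
         details = result$details)
  } else {
    result
  }
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
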