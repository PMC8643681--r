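# Shared fixtures and independent oracles.

ptptk2 <- function() plasmid_spec("pTPTK2", 5455)

# IUPAC nucleotide classes written out independently of the implementation
# (which derives them from Biostrings::IUPAC_CODE_MAP).
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Brute-force all-windows scan, one window at a time.
oracle_scan <- function(sequence, consensus, max_mismatches = 0) {
  scan_strand <- function(seq_str, strand, L, k) {
    chars <- strsplit(seq_str, "")[[1]]
    cons <- strsplit(consensus, "")[[1]]
    out <- list()
    for (s in seq_len(nchar(seq_str) - k + 1)) {
      mm <- 0L
      for (j in seq_len(k)) {
        if (!(chars[s + j - 1] %in% ORACLE_IUPAC[[cons[j]]])) mm <- mm + 1L
      }
      if (mm <= max_mismatches) {
        pos <- if (strand == "+") s else L - s - k + 2L
        out[[length(out) + 1L]] <- data.frame(
          position = pos, strand = strand, mismatches = mm)
      }
    }
    do.call(rbind, out)
  }
  k <- nchar(consensus)
  L <- nchar(sequence)
  if (L < k) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  hits <- rbind(scan_strand(sequence, "+", L, k),
                scan_strand(oracle_revcomp(sequence), "-", L, k))
  if (is.null(hits)) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Zero-mismatch oracle via regular expressions (overlapping matches).
oracle_scan_regex <- function(sequence, consensus) {
  classes <- vapply(strsplit(consensus, "")[[1]], function(ch) {
    paste0("[", paste(ORACLE_IUPAC[[ch]], collapse = ""), "]")
  }, character(1))
  pat <- paste0("(?=", paste(classes, collapse = ""), ")")
  find <- function(x) {
    m <- gregexpr(pat, x, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  L <- nchar(sequence)
  k <- nchar(consensus)
  fwd <- find(sequence)
  rev <- find(oracle_revcomp(sequence))
  out <- rbind(
    data.frame(position = fwd,
               strand = rep("+", length(fwd))),
    data.frame(position = L - rev - k + 2L,
               strand = rep("-", length(rev))))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build a ladder whose major band sits `steps` positions from a reference
# band of known writhe.
toy_ladder <- function(n_bands, major_index) {
  int <- rep(2, n_bands)
  int[major_index] <- 10
  band_ladder(seq_len(n_bands), int)
}
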