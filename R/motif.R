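# IUPAC consensus motif scanning over both strands with a mismatch budget.

iupac_classes <- function() {
  strsplit(Biostrings::IUPAC_CODE_MAP, "")
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Slides the consensus over both strands of the sequence and reports every
#' window matching with at most `max_mismatches` mismatches. A position
#' matches when the sequence base belongs to the IUPAC class of the
#' consensus symbol (an `N` base in the sequence matches no class and
#' always counts as a mismatch). Coordinates are 1-based; reverse-strand
#' hits are matched against the reverse complement but reported with the
#' forward coordinate of the window start.
#'
#' @param sequence Nucleotide sequence: a single character string over
#'   A/C/G/T/N (case-insensitive) or a [Biostrings::DNAString].
#' @param consensus Consensus motif using IUPAC nucleotide codes, e.g.
#'   `"TTTGTGTABSTGBTTATGTAGGT"`.
#' @param max_mismatches Maximum number of mismatching positions
#'   (default 0).
#' @return Data frame with columns `position` (forward 1-based window
#'   start), `strand` (`"+"`/`"-"`) and `mismatches`, sorted by position.
#' @examples
#' scan_consensus("AATTTGTGTAGCTGGTTATGTAGGTAA", "TTTGTGTABSTGBTTATGTAGGT")
#' @export
scan_consensus <- function(sequence, consensus, max_mismatches = 0) {
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(consensus), length(consensus) == 1L,
            max_mismatches >= 0)
  sequence <- toupper(sequence)
  consensus <- toupper(consensus)
  classes <- iupac_classes()
  cons <- strsplit(consensus, "")[[1]]
  if (length(cons) == 0L) stop("empty consensus", call. = FALSE)
  bad <- setdiff(cons, names(classes))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s) in consensus: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  seq_chars <- strsplit(sequence, "")[[1]]
  bad_seq <- setdiff(seq_chars, c("A", "C", "G", "T", "N"))
  if (length(bad_seq) > 0L) {
    stop("sequence contains non-A/C/G/T/N characters: ",
         paste(unique(bad_seq), collapse = ", "), call. = FALSE)
  }
  k <- length(cons)
  L <- length(seq_chars)
  empty <- data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0))
  if (L < k) return(empty)

  scan_one <- function(chars) {
    nw <- length(chars) - k + 1L
    mm <- integer(nw)
    for (j in seq_len(k)) {
      ok <- chars[j:(nw + j - 1L)] %in% classes[[cons[j]]]
      mm <- mm + !ok
    }
    hit <- which(mm <= max_mismatches)
    data.frame(window = hit, mismatches = mm[hit])
  }

  fwd <- scan_one(seq_chars)
  rc <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sequence))),
    "")[[1]]
  rev <- scan_one(rc)
  out <- rbind(
    if (nrow(fwd) > 0L)
      data.frame(position = fwd$window, strand = "+",
                 mismatches = fwd$mismatches) else empty,
    if (nrow(rev) > 0L)
      data.frame(position = L - rev$window - k + 2L, strand = "-",
                 mismatches = rev$mismatches) else empty
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Scan FASTA sequences for a consensus motif
#'
#' Applies [scan_consensus()] to every record of a FASTA file and returns
#' hits in a BED-like table with 1-based inclusive coordinates.
#'
#' @param fasta_file Path to a FASTA file.
#' @param consensus IUPAC consensus motif.
#' @param max_mismatches Maximum mismatches per window.
#' @return Data frame with columns `seqname`, `start`, `end` (1-based
#'   inclusive), `strand`, `mismatches`.
#' @export
scan_fasta <- function(fasta_file, consensus, max_mismatches = 0) {
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  k <- nchar(consensus)
  hits <- lapply(seq_along(seqs), function(i) {
    h <- scan_consensus(as.character(seqs[[i]]), consensus, max_mismatches)
    if (nrow(h) == 0L) return(NULL)
    data.frame(seqname = names(seqs)[i], start = h$position,
               end = h$position + k - 1L, strand = h$strand,
               mismatches = h$mismatches)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(seqname = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       mismatches = integer(0))
  }
  hits
}
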