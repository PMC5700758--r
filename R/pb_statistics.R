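# Per-position PB frequencies, the Neq entropy profile, and the data
# behind the frequency map and logo representations.

# resolve an inclusive residue frame against the available residue ids;
# fatal on an empty or out-of-range frame
.resolve_frame <- function(ids, residue_min = NULL, residue_max = NULL) {
  lo <- if (is.null(residue_min)) min(ids) else as.integer(residue_min)
  hi <- if (is.null(residue_max)) max(ids) else as.integer(residue_max)
  if (is.na(lo) || is.na(hi) || lo > hi || lo < min(ids) || hi > max(ids)) {
    stop("invalid residue frame ", lo, "-", hi, "; valid range is ",
         min(ids), "-", max(ids), " with residue-min <= residue-max")
  }
  c(lo, hi)
}

#' Per-position PB frequencies
#'
#' Normalises each row of a count matrix to frequencies summing to 1. Rows
#' with zero total count (positions that are `Z` in every conformation,
#' e.g. the two first and two last residues) are returned as all-zero and
#' flagged through the `"support"` attribute.
#'
#' @param matrix A `pb_count` object.
#' @return An x-by-16 numeric matrix of frequencies in `[0, 1]`, columns
#'   `a`..`p`, with attributes `"support"` (integer row totals) and
#'   `"residue_ids"`.
#' @export
pb_frequencies <- function(matrix) {
  stopifnot(inherits(matrix, "pb_count"))
  support <- rowSums(matrix$counts)
  denom <- ifelse(support > 0, support, 1)
  freq <- matrix$counts / denom
  attr(freq, "support") <- as.integer(support)
  attr(freq, "residue_ids") <- matrix$residue_ids
  freq
}

#' Equivalent number of Protein Blocks (Neq)
#'
#' The Neq of a frequency distribution f over the 16 PBs is
#' `exp(-sum(f * log(f)))`, the exponential of its Shannon entropy (natural
#' logarithm; terms with `f = 0` contribute 0). It is the equivalent number
#' of PBs sampled at a position: 1 when a single PB is always observed
#' (a locally rigid backbone), 16 when all PBs occur with frequency 1/16,
#' and k when k PBs occur in equal proportions 1/k. High Neq flags local
#' deformability. Positions with zero support (all-`Z`) return 0 by
#' convention, distinguishing "never assigned" from "rigid".
#'
#' @param f A numeric vector of 16 frequencies, or a frequency matrix as
#'   returned by [pb_frequencies()] (one value per row), or a `pb_count`
#'   object.
#' @return Numeric vector of Neq values.
#' @examples
#' pb_neq(rep(1 / 16, 16))          # 16: maximally variable
#' pb_neq(c(1, rep(0, 15)))         # 1: rigid
#' pb_neq(c(rep(1 / 5, 5), rep(0, 11)))  # 5
#' @export
pb_neq <- function(f) {
  if (inherits(f, "pb_count")) f <- pb_frequencies(f)
  if (is.matrix(f)) {
    return(apply(f, 1L, pb_neq))
  }
  stopifnot(is.numeric(f), all(f >= 0))
  if (sum(f) == 0) return(0)
  p <- f[f > 0]
  exp(-sum(p * log(p)))
}

#' Neq profile along the sequence
#'
#' Computes Neq for every residue position of a count matrix, optionally
#' restricted to an inclusive residue frame.
#'
#' @param matrix A `pb_count` object.
#' @param residue_min,residue_max Optional inclusive bounds on the residue
#'   numbers to keep.
#' @return A `neq_profile`: data frame with columns `resid` and `neq`.
#' @examples
#' m <- pb_count(rep(c("ZZmmmZZ", "ZZmmdZZ"), 5))
#' neq_profile(m)
#' @export
neq_profile <- function(matrix, residue_min = NULL, residue_max = NULL) {
  stopifnot(inherits(matrix, "pb_count"))
  ids <- matrix$residue_ids
  frame <- .resolve_frame(ids, residue_min, residue_max)
  keep <- ids >= frame[1L] & ids <= frame[2L]
  out <- data.frame(resid = ids[keep],
                    neq = unname(pb_neq(matrix)[keep]))
  class(out) <- c("neq_profile", "data.frame")
  out
}

#' Write an Neq profile as a two-column text file
#'
#' @param profile An `neq_profile` from [neq_profile()].
#' @param path Output file path (see [pb_output_name()] for the
#'   conventional `<prefix>.PB.Neq[.<min>-<max>]` naming).
#' @return `path`, invisibly.
#' @export
write_neq <- function(profile, path) {
  lines <- c(sprintf("%-8s %8s", "resid", "Neq"),
             sprintf("%-8d %8.4f", profile$resid, profile$neq))
  writeLines(lines, path)
  invisible(path)
}

#' Frequency grid for the PB distribution map
#'
#' The data behind the PB distribution heatmap: the per-position frequency
#' of each PB along the protein sequence, positions as rows and the 16 PBs
#' `a`..`p` as columns. A value of 0 means the PB is never sampled at that
#' position and 1 that it is always found there.
#'
#' @param matrix A `pb_count` object.
#' @return An x-by-16 matrix of values in `[0, 1]` (identical to
#'   [pb_frequencies()]).
#' @export
map_data <- function(matrix) {
  pb_frequencies(matrix)
}

#' Letter heights for the PB logo representation
#'
#' For each position, the PBs observed there with their frequencies sorted
#' in decreasing order; the height of each letter in a logo is proportional
#' to its frequency at that position.
#'
#' @inheritParams neq_profile
#' @return A named list, one element per position (named by residue
#'   number), each a named numeric vector of per-PB frequencies sorted
#'   decreasingly (zero-frequency PBs omitted). Heights at a position sum
#'   to at most 1 (less than 1 only where some conformations are `Z`).
#' @export
logo_data <- function(matrix, residue_min = NULL, residue_max = NULL) {
  stopifnot(inherits(matrix, "pb_count"))
  freq <- pb_frequencies(matrix)
  ids <- matrix$residue_ids
  frame <- .resolve_frame(ids, residue_min, residue_max)
  keep <- which(ids >= frame[1L] & ids <= frame[2L])
  out <- lapply(keep, function(i) {
    row <- freq[i, ]
    row <- row[row > 0]
    sort(row, decreasing = TRUE)
  })
  names(out) <- ids[keep]
  out
}

#' Conventional output file name
#'
#' Builds the pipeline's output names: `<prefix>.PB.fasta`,
#' `<prefix>.PB.count`, `<prefix>.PB.Neq` (with a `.<min>-<max>` suffix
#' when a residue frame is used), and image names such as
#' `<prefix>.PB.map.png`.
#'
#' @param prefix Output prefix (possibly including a directory).
#' @param what One of `"fasta"`, `"count"`, `"Neq"`, `"map"`, `"logo"`.
#' @param residue_min,residue_max Optional residue frame for framed
#'   outputs.
#' @param ext Image extension for `"map"`/`"logo"`/image form of `"Neq"`.
#' @return The output file name as a string.
#' @export
pb_output_name <- function(prefix, what = c("fasta", "count", "Neq",
                                            "map", "logo"),
                           residue_min = NULL, residue_max = NULL,
                           ext = "png") {
  what <- match.arg(what)
  frame <- if (!is.null(residue_min) || !is.null(residue_max)) {
    paste0(".", residue_min, "-", residue_max)
  } else ""
  switch(what,
         fasta = paste0(prefix, ".PB.fasta"),
         count = paste0(prefix, ".PB.count"),
         Neq = paste0(prefix, ".PB.Neq", frame),
         map = paste0(prefix, ".PB.map", frame, ".", ext),
         logo = paste0(prefix, ".PB.logo", frame, ".", ext))
}
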