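# Accumulating PB sequences into per-position count matrices, and the
# whitespace-delimited count-table text format.

#' Read PB sequences from FASTA files
#'
#' Reads one or more FASTA files of PB sequences (as written by
#' [write_pb_fasta()]), concatenating records across files in argument
#' order. Letters are validated against the PB alphabet `a`..`p` plus `Z`,
#' and all sequences must have equal length (positions are compared across
#' conformations of the same protein).
#'
#' @param paths Character vector of FASTA file paths.
#' @return Named character vector of PB sequences.
#' @export
read_pb_fasta <- function(paths) {
  stopifnot(length(paths) >= 1L)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("cannot read FASTA file(s): ", paste(missing, collapse = ", "))
  }
  sets <- lapply(paths, Biostrings::readBStringSet)
  set <- do.call(c, sets)
  seqs <- as.character(set)

  valid <- PB_ALPHABET
  for (k in seq_along(seqs)) {
    ch <- strsplit(seqs[k], "")[[1L]]
    bad <- which(!(ch %in% valid))
    if (length(bad) > 0) {
      stop("invalid PB letter '", ch[bad[1L]], "' in record '",
           names(seqs)[k], "' at position ", bad[1L],
           " (alphabet is a..p and Z)")
    }
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("PB sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "),
         "); positions would not be comparable")
  }
  seqs
}

#' Count PB occurrences per residue position
#'
#' Builds the x-by-16 occurrence matrix of an ensemble: element `[i, b]` is
#' the number of sequences carrying PB `b` at position `i`. The dummy block
#' `Z` is counted in no column, so a row sums to less than the number of
#' sequences exactly where some sequences are unassigned; the number of `Z`
#' at position i is recoverable as `n_sequences - rowSums(counts)[i]`.
#'
#' @param sequences Named character vector of equal-length PB sequences.
#' @param residue_ids Optional integer vector of residue numbers for the
#'   rows; defaults to sequential `1..x`.
#' @return A `pb_count` object: list with `counts` (x-by-16 integer matrix,
#'   columns `a`..`p`), `residue_ids`, and `n_sequences`.
#' @examples
#' m <- pb_count(rep("ZZmmmZZ", 10))
#' m$counts[3:5, "m"]  # all 10
#' @export
pb_count <- function(sequences, residue_ids = NULL) {
  if (length(sequences) == 0L) stop("no PB sequences to count")
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L) {
    stop("PB sequences have unequal lengths")
  }
  x <- lens[1L]
  mat <- matrix(0L, nrow = x, ncol = 16L,
                dimnames = list(NULL, letters[1:16]))
  chars <- matrix(unlist(strsplit(unname(sequences), "")), nrow = x)
  for (b in letters[1:16]) {
    mat[, b] <- as.integer(rowSums(chars == b))
  }
  bad <- !(chars %in% PB_ALPHABET)
  if (any(bad)) {
    stop("invalid PB letter '", chars[which(bad)[1L]], "' in input")
  }
  if (is.null(residue_ids)) residue_ids <- seq_len(x)
  stopifnot(length(residue_ids) == x)
  structure(list(counts = mat, residue_ids = as.integer(residue_ids),
                 n_sequences = length(sequences)),
            class = "pb_count")
}

#' @export
print.pb_count <- function(x, ...) {
  cat("pb_count:", nrow(x$counts), "positions x 16 PBs,",
      x$n_sequences, "sequences\n")
  invisible(x)
}

#' Write / read a PB count matrix as a text table
#'
#' The on-disk format is a whitespace-delimited table with one header row of
#' the 16 PB letters, and one data row per residue whose first column is the
#' residue number followed by the 16 counts. `read_pb_count(write_pb_count(m))`
#' reproduces `m` exactly.
#'
#' @param matrix A `pb_count` object.
#' @param path File path.
#' @return `write_pb_count` returns `path` invisibly; `read_pb_count`
#'   returns a `pb_count` object. The file does not store the ensemble
#'   size, so `n_sequences` is reconstructed as the maximum row total
#'   unless supplied; per-row frequencies and Neq are unaffected by this
#'   choice.
#' @export
write_pb_count <- function(matrix, path) {
  stopifnot(inherits(matrix, "pb_count"))
  widths <- pmax(nchar(format(max(matrix$counts), scientific = FALSE)),
                 nchar(max(matrix$residue_ids)), 6L)
  fmt <- paste0("%", widths, "s")
  header <- paste0(sprintf(fmt, ""),
                   paste(sprintf(fmt, letters[1:16]), collapse = ""))
  rows <- vapply(seq_len(nrow(matrix$counts)), function(i) {
    paste0(sprintf(fmt, matrix$residue_ids[i]),
           paste(sprintf(fmt, matrix$counts[i, ]), collapse = ""))
  }, character(1))
  tryCatch(writeLines(c(header, rows), path),
           error = function(e) stop("cannot write count table to ", path,
                                    ": ", conditionMessage(e),
                                    call. = FALSE))
  invisible(path)
}

#' @rdname write_pb_count
#' @param n_sequences Total number of sequences behind the counts; if `NULL`
#'   (the default) it is reconstructed as the maximum row sum.
#' @export
read_pb_count <- function(path, n_sequences = NULL) {
  if (!file.exists(path)) stop("cannot read count table: ", path)
  tab <- tryCatch(utils::read.table(path, header = TRUE,
                                    check.names = FALSE),
                  error = function(e) stop("malformed count table ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (ncol(tab) != 16L ||
      !identical(colnames(tab), letters[1:16])) {
    stop("malformed count table ", path,
         ": expected a header of the 16 PB letters a..p plus a residue",
         " number column, got ", ncol(tab), " columns")
  }
  vals <- as.matrix(tab)
  if (any(vals != round(vals)) || any(vals < 0)) {
    bad_row <- which(apply(vals != round(vals) | vals < 0, 1L, any))[1L]
    stop("malformed count table ", path, ": non-integer or negative cell",
         " in data row ", bad_row)
  }
  resids <- as.integer(rownames(tab))
  if (anyNA(resids)) {
    stop("malformed count table ", path, ": non-integer residue number")
  }
  counts <- matrix(as.integer(vals), ncol = 16L,
                   dimnames = list(NULL, letters[1:16]))
  if (is.null(n_sequences)) n_sequences <- max(rowSums(counts), 0L)
  structure(list(counts = counts, residue_ids = resids,
                 n_sequences = as.integer(n_sequences)),
            class = "pb_count")
}
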