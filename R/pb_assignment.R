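# Protein Block assignment: 8-angle windows, RMSDA metric, nearest
# prototype with dummy block Z, FASTA output.

#' Extract the 8-dihedral window of a residue
#'
#' Assigning a PB to residue n uses the five residues n-2 .. n+2, described
#' by eight dihedral angles in the order psi(n-2), phi(n-1), psi(n-1),
#' phi(n), psi(n), phi(n+1), psi(n+1), phi(n+2).
#'
#' @param series A `dihedral_series` from [phi_psi()].
#' @param n Residue index (1-based position in the series).
#' @return Numeric vector of 8 angles, named by window slot. Entries are
#'   `NA` where the underlying angle is undefined or where the window
#'   extends past the chain ends; the window is complete iff no entry is
#'   `NA` (see [is_complete_window()]).
#' @export
pb_window <- function(series, n) {
  len <- nrow(series)
  stopifnot(n >= 1L, n <= len)
  w <- rep(NA_real_, 8L)
  names(w) <- colnames(pb_reference())
  if (n - 2L >= 1L) w[1L] <- series$psi[n - 2L]
  if (n - 1L >= 1L) {
    w[2L] <- series$phi[n - 1L]
    w[3L] <- series$psi[n - 1L]
  }
  w[4L] <- series$phi[n]
  w[5L] <- series$psi[n]
  if (n + 1L <= len) {
    w[6L] <- series$phi[n + 1L]
    w[7L] <- series$psi[n + 1L]
  }
  if (n + 2L <= len) w[8L] <- series$phi[n + 2L]
  w
}

#' @rdname pb_window
#' @param window A vector as returned by `pb_window()`.
#' @export
is_complete_window <- function(window) {
  length(window) == 8L && !anyNA(window)
}

#' Root Mean Square Deviation Angle between two dihedral vectors
#'
#' The dissimilarity used for nearest-prototype PB assignment: a Euclidean
#' distance on angles, `sqrt(mean(d^2))` where `d` is the minimal signed
#' angular difference between paired components, mapped into
#' `(-180, 180]` degrees. Symmetric, and zero iff the vectors are equal
#' modulo 360 degrees.
#'
#' @param v,ref Numeric vectors of equal length (degrees).
#' @return Non-negative dissimilarity in degrees.
#' @examples
#' rmsda(c(10, rep(0, 7)), rep(0, 8))  # sqrt(100/8)
#' @export
rmsda <- function(v, ref) {
  stopifnot(length(v) == length(ref))
  d <- wrap_angle(v - ref)
  sqrt(mean(d^2))
}

#' Assign Protein Blocks to every residue of a dihedral series
#'
#' For each residue with a complete 8-angle window, assigns the PB whose
#' reference angles have the smallest RMSDA to the window; ties are broken
#' by alphabetical order of the PB letters. Residues whose window is
#' incomplete (chain termini, chain breaks, missing atoms) receive the
#' dummy block `Z`; in particular the first two and last two residues of
#' any continuous chain are always `Z`, and chains shorter than five
#' residues are all-`Z`.
#'
#' @param series A `dihedral_series` from [phi_psi()], or a
#'   [backbone_chain] (converted internally).
#' @param reference A PB reference table as from [pb_reference()].
#' @return A single string over the alphabet `a`..`p`, `Z`, one character
#'   per residue, named by the series label when available.
#' @examples
#' helix <- build_backbone(phi = rep(-57, 9), psi = rep(-47, 9))
#' pb_assign(helix)  # interior residues -> "m"
#' @export
pb_assign <- function(series, reference = pb_reference()) {
  if (inherits(series, "backbone_chain")) series <- phi_psi(series)
  stopifnot(nrow(reference) == 16L, ncol(reference) == 8L)
  len <- nrow(series)
  letters_out <- rep("Z", len)
  for (n in seq_len(len)) {
    w <- pb_window(series, n)
    if (!is_complete_window(w)) next
    d <- apply(reference, 1L, rmsda, v = w)
    letters_out[n] <- rownames(reference)[which.min(d)]  # ties: first = a..p
  }
  seq <- paste(letters_out, collapse = "")
  lab <- attr(series, "label")
  if (!is.null(lab)) names(seq) <- lab
  seq
}

#' Assign Protein Blocks to a collection of chains
#'
#' @param chains A list of [backbone_chain] objects, as returned by
#'   [read_structure()] or [read_trajectory()].
#' @inheritParams pb_assign
#' @return A named character vector of PB sequences, one per chain, in
#'   input order.
#' @export
pb_assign_chains <- function(chains, reference = pb_reference()) {
  stopifnot(length(chains) > 0)
  out <- vapply(chains, function(ch) unname(pb_assign(ch, reference)),
                character(1))
  names(out) <- vapply(chains, function(ch) ch$label, character(1))
  out
}

#' Write PB sequences to a FASTA file
#'
#' One record per conformation, header `><label>`, sequence wrapped at 60
#' characters. Duplicate labels are made unique by appending a numeric
#' suffix.
#'
#' @param sequences Named character vector of PB sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pb_fasta <- function(sequences, path) {
  if (length(sequences) == 0L) {
    warning("no PB sequences to write; creating empty file ", path)
    file.create(path)
    return(invisible(path))
  }
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("sequence ", seq_along(sequences))
  if (anyDuplicated(nm)) nm <- make.unique(nm, sep = " #")
  set <- Biostrings::BStringSet(unname(sequences))
  names(set) <- nm
  tryCatch(Biostrings::writeXStringSet(set, path, width = 60L),
           error = function(e) stop("cannot write FASTA to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}
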