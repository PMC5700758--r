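# Reading protein structures and MD ensembles into backbone chains.
#
# File parsing is delegated to bio3d (PDB, PDBx/mmCIF, DCD, Amber NetCDF);
# this module extracts the N/CA/C backbone, applies altloc and heteroatom
# policy, and splits atoms into one backbone_chain per (model/frame, chain).

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Backbone chain object
#'
#' A `backbone_chain` holds the N/CA/C backbone of one protein chain from one
#' model (or trajectory frame): residue numbers and names as they appear in
#' the source file, and one n x 3 coordinate matrix per backbone atom type,
#' with `NA` rows where an atom is missing.
#'
#' @param resid Integer vector of residue numbers (verbatim from the source).
#' @param resname Character vector of 3-letter residue codes.
#' @param N,CA,C Numeric n x 3 matrices of coordinates in Angstrom; rows of
#'   `NA` mark absent atoms.
#' @param label Provenance label, e.g. `"file.pdb | model 2 | chain A"`.
#' @return An object of class `backbone_chain`.
#' @export
backbone_chain <- function(resid, resname, N, CA, C, label = "chain") {
  n <- length(resid)
  as_coord <- function(m) {
    m <- matrix(as.numeric(m), ncol = 3)
    stopifnot(nrow(m) == n)
    if (any(is.infinite(m))) stop("coordinates must be finite")
    m
  }
  structure(list(label = as.character(label),
                 resid = as.integer(resid),
                 resname = as.character(resname),
                 N = as_coord(N), CA = as_coord(CA), C = as_coord(C)),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat("backbone_chain:", x$label, "\n")
  cat(" ", length(x$resid), "residues, resid",
      min(x$resid), "to", max(x$resid), "\n")
  missing <- sum(is.na(x$N[, 1])) + sum(is.na(x$CA[, 1])) +
    sum(is.na(x$C[, 1]))
  if (missing > 0) cat("  missing backbone atoms:", missing, "\n")
  invisible(x)
}

#' @export
length.backbone_chain <- function(x) length(x$resid)

#' Read a protein structure file into backbone chains
#'
#' Parses a PDB or PDBx/mmCIF file and returns one [backbone_chain] per
#' (model, chain) pair, models in file order then chains in file order. Only
#' atoms named N, CA and C of amino-acid records are retained; heteroatoms
#' and waters are excluded, except residues named in `include_het`
#' (selenomethionine by default). For alternate locations the
#' highest-occupancy conformer is kept (first-listed on ties). Residues with
#' missing backbone atoms are kept, with `NA` coordinates, so that
#' downstream assignment produces the dummy block `Z` there.
#'
#' @param path Path to the structure file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`. `"auto"` detects from
#'   the extension (`.pdb`/`.ent` -> pdb, `.cif`/`.mmcif` -> mmcif).
#' @param include_het Character vector of HETATM residue names to treat as
#'   amino acids. Default `"MSE"`.
#' @return A list of [backbone_chain] objects, named by their labels.
#' @examples
#' path <- make_ensemble(phi = rep(-57, 8), psi = rep(-47, 8),
#'                       n_frames = 3, seed = 1,
#'                       path = tempfile(fileext = ".pdb"))
#' chains <- read_structure(path)
#' length(chains)  # 3 models -> 3 chains
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           include_het = "MSE") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read structure file: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = , ent = "pdb",
                     cif = , mmcif = "mmcif",
                     stop("cannot auto-detect format from extension '.",
                          ext, "' for ", path))
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  .chains_from_bio3d(parsed$atom, parsed$xyz, source_name = basename(path),
                     frame_word = "model", include_het = include_het)
}

#' Read an MD topology + trajectory pair into backbone chains
#'
#' Reads atom metadata from a PDB topology and coordinates from a trajectory
#' file, returning one [backbone_chain] per (frame, chain), frames in
#' trajectory order with 1-based frame numbers in the labels. Supported
#' trajectory formats: DCD (`.dcd`), Amber NetCDF (`.nc`/`.ncdf`), and
#' multi-model PDB (`.pdb`). Solvent and other non-protein atoms present in
#' the topology are excluded from the backbone chains.
#'
#' @param topology Path to a PDB file describing the atoms.
#' @param trajectory Path to the trajectory file (same atoms, any number of
#'   frames).
#' @inheritParams read_structure
#' @return A list of [backbone_chain] objects, named by their labels.
#' @export
read_trajectory <- function(topology, trajectory, include_het = "MSE") {
  if (!file.exists(topology)) stop("cannot read topology file: ", topology)
  if (!file.exists(trajectory)) {
    stop("cannot read trajectory file: ", trajectory)
  }
  top <- bio3d::read.pdb(topology, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  ext <- tolower(tools::file_ext(trajectory))
  xyz <- switch(ext,
    dcd = bio3d::read.dcd(trajectory, verbose = FALSE),
    nc = , ncdf = {
      res <- NULL
      utils::capture.output(res <- bio3d::read.ncdf(trajectory))
      res
    },
    pdb = bio3d::read.pdb(trajectory, multi = TRUE, rm.alt = FALSE,
                          verbose = FALSE)$xyz,
    stop("unsupported trajectory format: .", ext,
         " (supported: .dcd, .nc, .pdb)"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(top$atom)) {
    stop("atom-count mismatch between topology (", nrow(top$atom),
         " atoms) and trajectory (", ncol(xyz) / 3, " atoms)")
  }
  .chains_from_bio3d(top$atom, xyz, source_name = basename(trajectory),
                     frame_word = "frame", include_het = "MSE")
}

# Shared backbone extraction from a bio3d atom table plus a frames x (3n)
# coordinate matrix.
.chains_from_bio3d <- function(atom, xyz, source_name, frame_word,
                               include_het = "MSE") {
  xyz <- matrix(as.numeric(xyz), ncol = 3L * nrow(atom))
  atom$chain[is.na(atom$chain) | atom$chain == ""] <- " "
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  atom$o[is.na(atom$o)] <- 1

  if (any(atom$insert != "")) {
    warning("insertion codes present in ", source_name,
            "; keeping file order, storing integer residue numbers only")
  }

  chains_before <- unique(atom$chain[atom$type %in% c("ATOM", "HETATM")])

  is_protein <- (atom$type == "ATOM" & atom$resid %in% .standard_aa) |
    atom$resid %in% include_het
  keep <- is_protein & atom$elety %in% c("N", "CA", "C")
  idx <- which(keep)
  if (length(idx) == 0L) stop("no protein backbone atoms found in ",
                              source_name)

  sub <- atom[idx, , drop = FALSE]
  sub$.orig <- idx

  # altloc policy: within one (chain, resno, insert, atom name) group keep
  # the highest-occupancy conformer, first-listed on ties
  grp <- paste(sub$chain, sub$resno, sub$insert, sub$elety, sep = "\r")
  best <- unlist(lapply(split(seq_len(nrow(sub)), grp)[unique(grp)],
                        function(i) i[which.max(sub$o[i])]),
                 use.names = FALSE)
  sub <- sub[sort(best), , drop = FALSE]

  # residues in file order within each chain
  res_key <- paste(sub$chain, sub$resno, sub$insert, sep = "\r")
  res_first <- !duplicated(res_key)
  res_order <- match(res_key, res_key[res_first])

  chains_after <- unique(sub$chain)
  lost <- setdiff(chains_before, chains_after)
  if (length(lost) > 0) {
    warning("chain(s) ", paste(shQuote(trimws(lost)), collapse = ", "),
            " in ", source_name,
            " contain no amino-acid residues; skipped")
  }

  n_frames <- nrow(xyz)
  out <- list()
  for (f in seq_len(n_frames)) {
    for (ch in chains_after) {
      rows <- which(sub$chain == ch)
      res_ids_here <- unique(res_order[rows])
      nres <- length(res_ids_here)
      coordN <- coordCA <- coordC <- matrix(NA_real_, nres, 3)
      resid <- integer(nres)
      resname <- character(nres)
      for (j in seq_len(nres)) {
        rrows <- rows[res_order[rows] == res_ids_here[j]]
        resid[j] <- sub$resno[rrows[1L]]
        resname[j] <- sub$resid[rrows[1L]]
        for (r in rrows) {
          a <- sub$.orig[r]
          xyz_r <- xyz[f, (3L * a - 2L):(3L * a)]
          switch(sub$elety[r],
                 N = coordN[j, ] <- xyz_r,
                 CA = coordCA[j, ] <- xyz_r,
                 C = coordC[j, ] <- xyz_r)
        }
      }
      label <- if (n_frames == 1L && frame_word == "model") {
        sprintf("%s | model 1 | chain %s", source_name, trimws(ch))
      } else {
        sprintf("%s | %s %d | chain %s", source_name, frame_word, f,
                trimws(ch))
      }
      out[[label]] <- backbone_chain(resid, resname, coordN, coordCA,
                                     coordC, label = label)
    }
  }
  out
}

#' Write backbone chains as a (multi-model) PDB file
#'
#' Writes one MODEL block per chain object (a single chain is written
#' without MODEL records). Atoms with missing coordinates are omitted from
#' the output. Intended for fixture generation and round-tripping backbone
#' data; only N/CA/C records are produced.
#'
#' @param chains A [backbone_chain] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(chains, path) {
  if (inherits(chains, "backbone_chain")) chains <- list(chains)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  multi <- length(chains) > 1L
  pad_name <- c(N = " N  ", CA = " CA ", C = " C  ")
  element <- c(N = "N", CA = "C", C = "C")
  for (m in seq_along(chains)) {
    ch <- chains[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    lines <- character(0)
    for (i in seq_along(ch$resid)) {
      for (at in c("N", "CA", "C")) {
        xyz <- ch[[at]][i, ]
        if (anyNA(xyz)) next
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, pad_name[[at]], ch$resname[i], ch$resid[i],
          xyz[1], xyz[2], xyz[3], 1, 0, element[[at]]))
      }
    }
    writeLines(lines, con)
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
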