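# Synthetic backbones with prescribed phi/psi angles, and multi-frame
# ensembles with controlled per-position variability. Coordinates are
# placed by sequential internal-coordinate (NeRF-style) construction with
# standard bond lengths and angles and a trans peptide bond (omega = 180).

.bond_length <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329)
.bond_angle <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7)

# Place atom D given atoms A, B, C, the bond length C-D, the bond angle
# B-C-D (degrees) and the torsion A-B-C-D (degrees).
.nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * cos(tor) * sin(pi - ang),
          bond * sin(tor) * sin(pi - ang))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Build a synthetic backbone with prescribed phi/psi angles
#'
#' Constructs N/CA/C Cartesian coordinates for a chain whose backbone
#' torsions match the given per-residue phi and psi targets, using standard
#' bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom), standard
#' bond angles and a fixed trans peptide bond (omega = 180 degrees). The
#' construction is deterministic, and recomputing [phi_psi()] on the
#' result reproduces the targets to well below 1e-6 degrees on interior
#' residues (`phi[1]` and `psi[n]` have no geometric meaning and are
#' ignored).
#'
#' @param phi,psi Numeric vectors of equal length: target torsions in
#'   degrees, one per residue.
#' @param resid Residue numbers (default `1..n`).
#' @param resname Residue name(s), recycled (default `"ALA"`).
#' @param label Chain label.
#' @return A [backbone_chain].
#' @examples
#' helix <- build_backbone(phi = rep(-57, 7), psi = rep(-47, 7))
#' phi_psi(helix)
#' @export
build_backbone <- function(phi, psi, resid = seq_along(phi),
                           resname = "ALA", label = "synthetic") {
  n <- length(phi)
  stopifnot(n >= 1L, length(psi) == n)
  resname <- rep_len(resname, n)
  Nm <- CAm <- Cm <- matrix(NA_real_, n, 3)

  # first residue in a canonical frame
  Nm[1L, ] <- c(0, 0, 0)
  CAm[1L, ] <- c(.bond_length[["N_CA"]], 0, 0)
  ang <- .bond_angle[["N_CA_C"]] * pi / 180
  Cm[1L, ] <- CAm[1L, ] + .bond_length[["CA_C"]] *
    c(-cos(ang), sin(ang), 0)

  for (i in seq_len(n - 1L)) {
    # N(i+1): torsion psi(i) about CA(i)-C(i)
    Nm[i + 1L, ] <- .nerf_place(Nm[i, ], CAm[i, ], Cm[i, ],
                                .bond_length[["C_N"]],
                                .bond_angle[["CA_C_N"]], psi[i])
    # CA(i+1): trans omega about C(i)-N(i+1)
    CAm[i + 1L, ] <- .nerf_place(CAm[i, ], Cm[i, ], Nm[i + 1L, ],
                                 .bond_length[["N_CA"]],
                                 .bond_angle[["C_N_CA"]], 180)
    # C(i+1): torsion phi(i+1) about N(i+1)-CA(i+1)
    Cm[i + 1L, ] <- .nerf_place(Cm[i, ], Nm[i + 1L, ], CAm[i + 1L, ],
                                .bond_length[["CA_C"]],
                                .bond_angle[["N_CA_C"]], phi[i + 1L])
  }
  backbone_chain(resid, resname, Nm, CAm, Cm, label = label)
}

#' Generate a synthetic conformational ensemble as a multi-model PDB
#'
#' Emulates an MD ensemble: each frame rebuilds the backbone from the base
#' phi/psi targets perturbed by independent wrapped-Gaussian noise, with
#' optional designed discrete states at chosen positions (each frame draws
#' one (phi, psi) row uniformly at random from that position's state
#' matrix). Positions with zero noise and no discrete states are rigid
#' across frames (expected Neq of 1 after assignment); noisy or multi-state
#' positions sample several PBs (Neq > 1).
#'
#' @param phi,psi Base per-residue torsion targets in degrees.
#' @param noise Wrapped-Gaussian standard deviation in degrees, a scalar or
#'   per-residue vector. Default 0 (all frames identical).
#' @param n_frames Number of frames (models) to generate.
#' @param seed Integer random seed; mandatory so ensembles are
#'   reproducible.
#' @param path Output PDB path.
#' @param discrete_states Optional list of designed multi-state blocks.
#'   Each entry is a list with `positions` (an integer vector of residue
#'   positions), `phi` and `psi` (k-by-length(positions) matrices): every
#'   frame draws one of the k states uniformly at random and overrides the
#'   base angles over the whole block coherently. Because a residue's PB is
#'   determined by the 8 dihedrals of its five-residue window, a block
#'   spanning positions `j-2 .. j+2` puts the letter at `j` fully under the
#'   state's control, which is how designed k-state (expected Neq = k)
#'   positions are constructed.
#' @return `path`, invisibly.
#' @examples
#' path <- make_ensemble(phi = rep(-57, 10), psi = rep(-47, 10),
#'                       noise = 5, n_frames = 4, seed = 42,
#'                       path = tempfile(fileext = ".pdb"))
#' length(read_structure(path))  # 4 frames
#' @export
#' @rdname make_ensemble
#' @param center Residue position whose PB letter the block controls.
#' @param angle_states A k-by-2 matrix of (phi, psi) pairs; state `s`
#'   sets every residue of the five-residue window `center-2 .. center+2`
#'   to `angle_states[s, ]`, so the letter at `center` is the PB nearest
#'   to the uniform repeat of that pair.
#' @return `pb_state_block` returns an entry for `discrete_states`.
#' @export
pb_state_block <- function(center, angle_states) {
  angle_states <- as.matrix(angle_states)
  stopifnot(ncol(angle_states) == 2L, center >= 3L)
  k <- nrow(angle_states)
  list(positions = (center - 2L):(center + 2L),
       phi = matrix(angle_states[, 1L], k, 5L),
       psi = matrix(angle_states[, 2L], k, 5L))
}

#' @export
make_ensemble <- function(phi, psi, noise = 0, n_frames, seed, path,
                          discrete_states = NULL) {
  n <- length(phi)
  stopifnot(n >= 1L, length(psi) == n, n_frames >= 1L)
  if (missing(seed)) stop("a fixed seed is mandatory for make_ensemble()")
  noise <- rep_len(noise, n)
  for (st in discrete_states) {
    stopifnot(is.matrix(st$phi), is.matrix(st$psi),
              ncol(st$phi) == length(st$positions),
              ncol(st$psi) == length(st$positions),
              nrow(st$phi) == nrow(st$psi),
              all(st$positions >= 1L), all(st$positions <= n))
  }
  set.seed(as.integer(seed))
  chains <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    fphi <- wrap_angle(phi + stats::rnorm(n, 0, noise))
    fpsi <- wrap_angle(psi + stats::rnorm(n, 0, noise))
    for (st in discrete_states) {
      k <- sample.int(nrow(st$phi), 1L)
      fphi[st$positions] <- st$phi[k, ]
      fpsi[st$positions] <- st$psi[k, ]
    }
    chains[[f]] <- build_backbone(fphi, fpsi,
                                  label = sprintf("frame %d", f))
  }
  write_backbone_pdb(chains, path)
  invisible(path)
}
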