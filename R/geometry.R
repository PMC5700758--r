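# Backbone torsion geometry: signed dihedrals and per-residue phi/psi.

# Maximum C(i)-N(i+1) distance (Angstrom) for two residues to be considered
# peptide-bonded; beyond this the chain is treated as broken and no dihedral
# spans the junction.
.peptide_bond_max <- 2.0

#' Signed torsion angle of four points
#'
#' Computes the dihedral angle of the chain `p1-p2-p3-p4` under the IUPAC
#' convention: 0 degrees for an exactly cis (eclipsed) arrangement, sign by
#' the right-hand rule about the `p2 -> p3` axis. Angles are reported in
#' `(-180, 180]` degrees, with exact trans geometry normalised to `+180`.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in Angstrom).
#' @return The torsion in degrees, or `NA` for degenerate geometry
#'   (a zero-length bond vector or three collinear points).
#' @examples
#' # planar trans arrangement
#' torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  if (anyNA(c(p1, p2, p3, p4))) return(NA_real_)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < .Machine$double.eps ||
      sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    return(NA_real_)  # degenerate: collinear triple or zero-length bond
  }
  ang <- atan2(sum(.cross3(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Wrap angles into (-180, 180] degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles mapped into `(-180, 180]`; `-180` normalises to `+180`.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * ceiling((x - 180) / 360)
  w[w <= -180] <- 180  # guard against floating-point landing on -180
  w
}

#' Backbone phi/psi dihedral angles of a chain
#'
#' Computes, for every residue of a [backbone_chain], the torsion angles
#' phi (`C(i-1), N(i), CA(i), C(i)`) and psi (`N(i), CA(i), C(i), N(i+1)`).
#' An angle is undefined (`NA`) when any required atom is absent or when the
#' peptide-bond continuity check between the two residues involved fails:
#' residues i and i+1 are continuous iff `resid(i+1) == resid(i) + 1` and,
#' when both atoms exist, `|C(i) - N(i+1)| <= 2.0` Angstrom. Consequently
#' phi of the first residue and psi of the last are always `NA`.
#'
#' @param chain A [backbone_chain].
#' @return A `dihedral_series`: a data frame with columns `resid`, `phi`,
#'   `psi` (degrees in `(-180, 180]` or `NA`), one row per residue in chain
#'   order, carrying the chain label as attribute `"label"`.
#' @examples
#' ch <- build_backbone(phi = rep(-57, 7), psi = rep(-47, 7))
#' phi_psi(ch)
#' @export
phi_psi <- function(chain) {
  stopifnot(inherits(chain, "backbone_chain"))
  n <- length(chain$resid)
  if (n == 0L) stop("empty backbone chain")
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)

  # continuity between residue i and i+1
  cont <- rep(FALSE, max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    if (chain$resid[i + 1L] != chain$resid[i] + 1L) next
    ci <- chain$C[i, ]
    ni1 <- chain$N[i + 1L, ]
    if (!anyNA(ci) && !anyNA(ni1) &&
        sqrt(sum((ci - ni1)^2)) > .peptide_bond_max) next
    cont[i] <- TRUE
  }

  for (i in seq_len(n)) {
    if (i > 1L && cont[i - 1L]) {
      phi[i] <- torsion_angle(chain$C[i - 1L, ], chain$N[i, ],
                              chain$CA[i, ], chain$C[i, ])
    }
    if (i < n && cont[i]) {
      psi[i] <- torsion_angle(chain$N[i, ], chain$CA[i, ],
                              chain$C[i, ], chain$N[i + 1L, ])
    }
  }

  out <- data.frame(resid = chain$resid, phi = phi, psi = psi)
  attr(out, "label") <- chain$label
  class(out) <- c("dihedral_series", "data.frame")
  out
}
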