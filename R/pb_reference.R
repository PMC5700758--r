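# Reference dihedral angles of the 16 Protein Blocks.
#
# Values transcribed verbatim from de Brevern, Etchebest & Hazout (2000)
# "Bayesian probabilistic approach for predicting backbone structures in
# terms of protein blocks", Proteins 41:271-287 -- the defining publication
# of the PB structural alphabet. Angles are in degrees, one row per block
# (a..p), columns in five-residue window order:
#   psi(n-2), phi(n-1), psi(n-1), phi(n), psi(n), phi(n+1), psi(n+1), phi(n+2)

.pb_angle_names <- c("psi(n-2)", "phi(n-1)", "psi(n-1)", "phi(n)",
                     "psi(n)", "phi(n+1)", "psi(n+1)", "phi(n+2)")

.pb_references <- matrix(c(
   41.14,   75.53,  13.92,  -99.80, 131.88,  -96.27, 122.08,  -99.68,  # a
  108.24,  -90.12, 119.54,  -92.21, -18.06, -128.93, 147.04,  -99.90,  # b
  -11.61, -105.66,  94.81, -106.09, 133.56, -106.93, 135.97, -100.63,  # c
  141.98, -112.79, 132.20, -114.79, 140.11, -111.05, 139.54, -103.16,  # d
  133.25, -112.37, 137.64, -108.13, 133.00,  -87.30, 120.54,   77.40,  # e
  116.40, -105.53, 129.32,  -96.68, 140.72,  -74.19, -26.65,  -94.51,  # f
    0.40,  -81.83,   4.91, -100.59,  85.50,  -71.65, 130.78,   84.98,  # g
  119.14, -102.58, 130.83,  -67.91, 121.55,   76.25,  -2.95,  -90.88,  # h
  130.68,  -56.92, 119.26,   77.85,  10.42,  -99.43, 141.40,  -98.01,  # i
  114.32, -121.47, 118.14,   82.88,-150.05,  -83.81,  23.35,  -85.82,  # j
  117.16,  -95.41, 140.40,  -59.35, -29.23,  -72.39, -25.08,  -76.16,  # k
  139.20,  -55.96, -32.70,  -68.51, -26.09,  -74.44, -22.60,  -71.74,  # l
  -39.62,  -64.73, -39.52,  -65.54, -38.88,  -66.89, -37.76,  -70.19,  # m
  -35.34,  -65.03, -38.12,  -66.34, -29.51,  -89.10,  -2.91,   77.90,  # n
  -45.29,  -67.44, -27.72,  -87.27,   5.13,   77.49,  30.71,  -93.23,  # o
  -27.09,  -86.14,   0.30,   59.85,  21.51,  -96.30, 132.67,  -92.91   # p
), nrow = 16, ncol = 8, byrow = TRUE,
   dimnames = list(letters[1:16], .pb_angle_names))

#' Reference dihedral-angle table of the 16 Protein Blocks
#'
#' The Protein Blocks (PBs) are 16 pentapeptide backbone prototypes, labelled
#' `a` to `p`, each defined by eight reference dihedral angles spanning a
#' five-residue window centred on the assigned residue: going from the psi
#' angle of residue n-2 to the phi angle of residue n+2. PB `m` is the
#' prototype of the central alpha-helix and PB `d` of the central beta-strand.
#'
#' @return A 16 x 8 numeric matrix of angles in degrees. Row names are the PB
#'   letters `a`..`p`; column names give the window slot
#'   (`psi(n-2)`, `phi(n-1)`, ..., `phi(n+2)`).
#'
#' @references de Brevern AG, Etchebest C, Hazout S (2000). Bayesian
#'   probabilistic approach for predicting backbone structures in terms of
#'   protein blocks. Proteins 41:271-287.
#'
#' @examples
#' ref <- pb_reference()
#' dim(ref)        # 16 blocks x 8 angles
#' ref["m", ]      # central alpha-helix prototype
#' @export
pb_reference <- function() {
  .pb_references
}

#' @rdname pb_reference
#' @format `PB_ALPHABET` is the character vector of the 16 PB letters plus the
#'   dummy block `Z` used where no PB can be assigned.
#' @export
PB_ALPHABET <- c(letters[1:16], "Z")
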