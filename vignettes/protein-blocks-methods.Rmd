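---
title: "Protein Blocks assignment and local deformability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein Blocks assignment and local deformability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteinBlocks)
```

## The model

A Protein Block (PB) is one of 16 pentapeptide backbone prototypes,
labelled `a` to `p`, each defined by eight reference dihedral angles. The
window describing residue $n$ runs over residues $n-2 \dots n+2$ in the
fixed order

$$v(n) = \big[\psi_{n-2},\ \varphi_{n-1},\ \psi_{n-1},\ \varphi_n,\
\psi_n,\ \varphi_{n+1},\ \psi_{n+1},\ \varphi_{n+2}\big],$$

and the residue receives the PB minimising the RMSDA dissimilarity

$$\mathrm{RMSDA}(v, r) = \sqrt{\tfrac{1}{8}\sum_{k=1}^{8} d(v_k, r_k)^2},$$

where $d$ is the minimal signed angular difference mapped into
$(-180^\circ, 180^\circ]$. Residues whose window cannot be completed —
the two residues at each chain end, neighbours of chain breaks, residues
with missing backbone atoms — receive the dummy block `Z`. PB `m` is the
central $\alpha$-helix prototype and `d` the central $\beta$-strand
prototype, which the package's self-consistency tests exploit: an ideal
helix backbone ($\varphi=-57^\circ$, $\psi=-47^\circ$) must assign `m` at
every interior position, an ideal extended strand
($\varphi=-120^\circ$, $\psi=135^\circ$) must assign `d`.

The 16 reference vectors are transcribed from the alphabet's defining
publication (de Brevern, Etchebest & Hazout 2000, *Proteins* 41:271–287)
and live in a single constants file (`R/pb_reference.R`). Since a
transcription error cannot be detected by internal consistency alone, the
tests check the three structural anchors above plus the zero-distance
property (a window equal to a prototype's angles is assigned that
prototype).

Over an ensemble of $N$ conformations of the same protein, per-position
counts give frequencies $f_x$ and the equivalent number of PBs

$$N_{eq} = \exp\Big(-\sum_{x=1}^{16} f_x \ln f_x\Big)$$

(natural logarithm; $0 \ln 0 := 0$). $N_{eq}$ ranges from 1 (one PB
always observed: locally rigid) to 16 (uniform sampling of all PBs), and
equals $k$ exactly when $k$ PBs occur in equal proportions. It measures
local *deformability*, which is distinct from *mobility*: a loop can
carry its residues over large distances (high RMSF) while every residue
keeps a single local conformation ($N_{eq} \approx 1$).

## Parameters that matter

* **RMSDA functional form.** Only "Euclidean distance on angles" is fixed
  by the method; the package uses the root-mean-square form. The argmin is
  invariant under any monotone rescaling (sum of squares, mean of squares,
  RMS), which a test asserts explicitly, so this choice cannot change an
  assignment.
* **Tie-breaking.** At exactly equal RMSDA the alphabetically first PB
  wins. Ties have measure zero on real data but the rule makes assignment
  deterministic and reproducible byte-for-byte.
* **Angle range.** All angles are reported in $(-180^\circ, 180^\circ]$
  with $-180^\circ$ normalised to $+180^\circ$, so exact trans geometry
  has one representation.
* **Chain-break rule.** Residues $i$ and $i+1$ are continuous iff
  `resid(i+1) == resid(i) + 1` *and*, when both atoms are present,
  $|C_i - N_{i+1}| \le 2.0$ Å (the peptide bond is $\approx 1.33$ Å; 2.0 Å
  tolerates distorted geometry while rejecting any true gap). Angles
  spanning a discontinuity are undefined, so no dihedral is ever computed
  across a gap. TER records are not needed for this decision: any genuine
  chain end manifests either as a numbering jump or as a long C–N
  distance, both of which this rule catches, which is why the reader
  delegates break detection to geometry rather than to record bookkeeping.
* **Heteroatom policy.** Only `N`/`CA`/`C` atoms of standard amino-acid
  records are read; waters and ligands are excluded. Residues named in
  `include_het` (default `MSE`, selenomethionine, routinely deposited as
  HETATM) are treated as amino acids. Altloc groups keep the
  highest-occupancy conformer, first-listed on ties. Insertion codes are
  tolerated (file order kept, integer residue number stored) with a
  warning — the package targets ensembles of one protein, where insertion
  codes are rare.
* **Missing atoms** never drop a residue: the residue stays, with `NA`
  coordinates, so the window rule degrades it (and its neighbours within
  reach) to `Z` rather than silently renumbering the chain.
* **$N_{eq}$ at all-`Z` positions.** Positions with zero assigned letters
  (for example the two first and two last residues) are written with the
  sentinel 0, keeping profiles full-length and visually distinct from
  rigid positions ($N_{eq}=1$); 0 is outside the attainable range
  $[1, 16]$, so no downstream consumer can mistake it for a measurement.
* **Residue numbering in count matrices** is sequential 1-based by
  default (`residue_ids` can carry source numbering when constructed
  explicitly); the text format stores whatever numbering the matrix
  carries.
* **Unequal sequence lengths** across FASTA records are a fatal error,
  not padded: positions of different-length sequences are not comparable,
  and silent padding would corrupt every downstream frequency.

## File formats and I/O

PDB and PDBx/mmCIF parsing, and DCD/Amber-NetCDF trajectory reading, are
delegated to `bio3d`; FASTA to `Biostrings`. Multi-model PDB files are
treated as ensembles (one chain object per model and chain). A topology +
trajectory pair is read as one chain per frame; an atom-count mismatch
between the two files is fatal. Gromacs XTC/TRR compressed trajectories
are not readable by any R parser this package depends on; DCD, Amber
NetCDF and multi-model PDB cover the common interchange route (every major
MD engine exports at least one of them).

Output naming follows the pipeline convention: `<prefix>.PB.fasta`,
`<prefix>.PB.count`, `<prefix>.PB.Neq` (`.PB.Neq.<min>-<max>` when a
residue frame is requested), and `.PB.map.*`/`.PB.logo.*` images. The
count file is a whitespace-delimited table with one header row of the 16
PB letters and one leading column of residue numbers; `Z` occurrences are
deliberately not a 17th column — the matrix is defined over the 16 PBs,
and the `Z` count at a position is recoverable as `n_sequences` minus the
row sum.

## The synthetic-ensemble generator

`build_backbone()` places N/CA/C atoms by sequential internal-coordinate
(NeRF) construction with standard bond lengths (N–CA 1.458 Å, CA–C
1.525 Å, C–N 1.329 Å), standard backbone bond angles and a fixed trans
peptide bond ($\omega = 180^\circ$); recomputed $\varphi/\psi$ reproduce
the prescribed targets to below $10^{-6}$ degrees, and in practice near
machine precision. `make_ensemble()` emulates an MD ensemble by rebuilding
the backbone each frame with independent wrapped-Gaussian perturbations of
the target angles, plus optional *designed discrete states*: because a
residue's letter is determined entirely by the eight dihedrals of its
five-residue window, a $k$-state block spanning positions $j-2 \dots j+2$
(`pb_state_block()`) puts the letter at $j$ fully under the state draw's
control, giving positions with known expected $N_{eq}$ ($=k$ for uniform
draws). A frame draws each block's state once, coherently across the
block — independent per-position draws would produce mixed windows and no
clean $k$-state letter.

What the generator does *not* emulate is worth stating: no side chains,
no sterics or energetics (self-intersection is possible and irrelevant
here), a rigid trans $\omega$, and angular noise that is independent
across residues and frames, unlike the correlated, autocorrelated
fluctuations of real MD. Passing tests on these fixtures therefore
validate the *assignment and statistics machinery* — window bookkeeping,
metric, counting, entropy — not the conformational realism of any
simulation.

## Problem sizes and numerical tolerances in the tests

The test suite works at sizes chosen to exercise every code path while
staying interactive: chains of 1–100 residues for the `Z`-padding law,
100 random quadruples for the torsion oracle (agreement demanded below
$10^{-9}$ degrees), 200 random windows for the exhaustive
nearest-prototype oracle (exact agreement), a 225-frame ensemble for the
end-to-end pipeline contract, and a 500-frame ensemble for $N_{eq}$
parameter recovery. For the recovery check the tolerance is not invented:
the sampling error of the plug-in $N_{eq}$ estimator at uniform-$k$ is
estimated by Monte Carlo (multinomial draws at the same $N$), and the
observed value must fall within three such standard errors of $k$, with
the estimator's small negative bias ($\approx -k(k-1)/2N$) absorbed by
centring on the Monte Carlo mean. Designed rigid positions must recover
$N_{eq} = 1$ exactly — with zero injected variability every frame yields
the identical letter, so any deviation would be a bookkeeping bug, not
noise.

## Known limitations

* No DNA/RNA chains, no symmetry/assembly expansion, no hydrogens.
* No $\omega$ or side-chain $\chi$ angles are reported.
* Count matrices with different residue ranges cannot be merged.
* The logo plot is a stacked-letter summary of the exact `logo_data()`
  heights, not a pixel replica of WebLogo output; the data contract, not
  the rendering, is the tested surface.
* Assignment is hard (argmin only): no fuzzy membership, no substitution
  scores.
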