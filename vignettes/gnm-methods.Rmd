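---
title: "Gaussian Network Model analysis with gnmkit: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian Network Model analysis with gnmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnmkit)
```

## The model

The Gaussian Network Model (GNM) treats a folded biomolecule as an elastic
network. Each amino acid contributes one node at its C-alpha; each
nucleotide contributes three nodes, at the P (phosphate), C4' (sugar) and
C2 (base) atoms, a representation that works well for nucleic acids and
protein–nucleic acid complexes. Identical springs of constant
$\gamma$ connect every pair of nodes within a cutoff $r_c$. Fluctuations
away from the energy minimum are assumed Gaussian and isotropic, so the
whole statistical mechanics of the network is governed by the Kirchhoff
(graph Laplacian) matrix $\Gamma$:

$$\Gamma_{ij} = \begin{cases} -1 & i \ne j,\ d_{ij} \le r_c \\ 0 & i \ne j,\ d_{ij} > r_c \\ -\sum_{k \ne i} \Gamma_{ik} & i = j. \end{cases}$$

Because the rows of $\Gamma$ sum to zero the matrix is singular, and
fluctuation statistics come from its Moore–Penrose pseudo-inverse,
assembled from the nonzero eigenpairs $(\lambda_k, \mathbf{u}_k)$, sorted
by ascending eigenvalue:

$$\Gamma^{-1} = \frac{3 k_B T}{\gamma} \sum_{k} \lambda_k^{-1} \mathbf{u}_k \mathbf{u}_k^{\mathsf T}.$$

The observables `gnmkit` reports are standard:

* **Mean-square fluctuations** $\langle (\Delta R_i)^2 \rangle \propto
  [\Gamma^{-1}]_{ii}$, compared with crystallographic B-factors through
  $B_i = (8\pi^2/3)\,\langle (\Delta R_i)^2 \rangle$.
* **Per-mode contributions** $[\mathbf C]_k = \lambda_k^{-1} \mathbf{u}_k
  \mathbf{u}_k^{\mathsf T}$; the softest mode ($k = 1$) always contributes
  most, and the diagonal of $[\mathbf C]_k$ is the *mode shape*.
* **Orientational cross-correlations** $C^{\mathrm{orient}}_{ij} =
  [\Gamma^{-1}]_{ij} / ([\Gamma^{-1}]_{ii}[\Gamma^{-1}]_{jj})^{1/2}$,
  computable over any subset of modes (default: the slowest three).
* **Collectivity** $\kappa_k = N^{-1} \exp(-\sum_i u_{k,i}^2 \ln
  u_{k,i}^2)$, between $1/N$ (single-node mode) and 1 (uniform mode).
* **Domain separation**: the sign of $u_{k,i}$ splits the structure into
  two anticorrelated subsets; sign changes along a chain (crossovers) mark
  interfaces that typically contain the global hinge.

All internal quantities are computed in units where $3 k_B T / \gamma = 1$;
only `theoretical_b_factors()` produces absolute squared-Angstrom values,
either with the unit scale or with a least-squares scalar fitted against
experimental B-factors (regression through the origin — the shape of the
profile, and hence every correlation, is scale-free).

## Parameters that matter

* **`cutoff` (r_c), default 7.3 Å.** The first inter-residue coordination
  shell of folded proteins lies at roughly 7.0–7.5 Å; 7.3 Å is this
  package's documented default inside that range, applied uniformly to all
  node pairs, including protein–nucleotide and nucleotide–nucleotide
  springs. The comparison is boundary-inclusive (a pair at exactly
  $r_c$ is a contact). A different uniform value can be passed everywhere
  the cutoff appears.
* **Spring constant.** Fixed at 1. It rescales fluctuation magnitudes but
  leaves their distribution, the cross-correlations and collectivities
  unchanged, which the test suite verifies by rescaling $\Gamma$.
* **Admission window, defaults 12–20000 nodes.** Mirrors database practice
  for structures that are too small for a meaningful mode spectrum or too
  large for routine processing. The upper cap is a soft limit exposed as
  an argument (`max_nodes`), since depositions slightly above it are still
  tractable. Depositions containing only C-alpha atoms are rejected by
  default; the network itself needs nothing else for proteins, so the
  filter can be switched off (`calpha_only_filter = FALSE`).
* **`zero_tol`, default 1e-8 (relative to the largest eigenvalue).**
  Eigenvalues below it are zero modes. Their count must equal the number
  of connected components of the contact graph; a mismatch is raised as an
  error rather than silently patched, because it indicates numerical
  failure.
* **`sign_tol`, default 1e-6 (relative to the largest eigenvector
  component).** Components below it get sign 0 in domain maps and count
  as crossover members; eigen-solvers do not produce exact zeros.
* **`store_fraction`, default 0.40.** The report stores the softest
  `ceiling(store_fraction * n_nonzero)` modes — "up to 40%" is read as a
  ceiling, and the count never exceeds the number of nonzero modes.
* **`n_fast`, default 10, and `top_q`, default 0.95.** Energy-localization
  peaks are read from the summed shape of the ten stiffest modes; the
  quantile threshold is this package's default for "peak".
* **Slow-mode minima window, default 5, strict.** Plateaus yield no
  minimum, the window never crosses a chain boundary, and chain termini
  (no neighbor on one side) are not eligible.
* **Collectivity reporting.** Per-mode collectivities are reported for the
  softest modes that jointly carry 1/10 of the fluctuation budget
  ($\sum \lambda_k^{-1}$), via `soft_mode_count(modes, 0.1)`.

## Structure input

PDB files are parsed with bio3d; the contracts layered on top are:

* **Model policy.** Exactly one model of a multi-model (e.g. NMR) file is
  used — the first by default.
* **Alternate locations.** For each atom the altloc with the highest
  occupancy is kept; ties go to the lexicographically smallest label, the
  common crystallographic convention.
* **Biological assemblies.** REMARK 350 BIOMT operators are applied
  operator-major; every generated copy receives a fresh, unique chain id
  (A–Z, a–z, 0–9, then two-character ids), with identity-operator copies
  keeping their original id. Operators that reproduce an existing copy's
  coordinates trigger a warning but both copies are kept, since the input
  file is the authority. Only the first assembly block is used unless an
  index is given.
* **Hetero groups.** Ligands and waters are never network nodes; modified
  standard residues are admitted through an explicit parent mapping
  (selenomethionine and friends by default). The choice to exclude
  ligand heavy atoms is deliberate: there is no accepted node rule for
  arbitrary chemistry, and contact topology among standard nodes is what
  the model is validated on.
* **Missing B-factors.** Structures without usable temperature factors are
  analyzed normally but excluded from experimental comparisons; the
  B-factor table is simply absent from their bundles.

## Numerical choices

* **Eigendecomposition** uses LAPACK's dense symmetric solver at every
  size. Dense decomposition of the largest admissible networks
  (~20000 nodes) is memory- and time-hungry but exact; a partial solver
  adds a second code path and an approximation boundary without changing
  any result below it, so the package stays with the single dense path.
* **Sign convention.** Each eigenvector is flipped so its
  largest-magnitude element is positive, with near-ties (within 1e-9)
  resolved to the lowest index. Eigen-solvers return arbitrary signs, and
  without a convention domain maps and TSV exports would not be
  reproducible across platforms.
* **Degenerate eigenvalues** (e.g. on symmetric rings) make individual
  eigenvectors solver-dependent inside the degenerate block. Scalar
  observables summed over a full block — fluctuations, cross-correlations
  over all modes, collectivity sums — are basis-invariant and tested as
  such; per-mode output inside a degenerate block is documented as
  non-unique.
* **Collectivity at zero components** adopts the $x \ln x \to 0$ limit:
  exactly-zero $u_{k,i}^2$ contributes nothing to the exponent.
* **Zero-range color rescale.** `write_colored_pdb()` maps values linearly
  to the printable B-column range [0, 99.99]; a constant vector maps to
  all zeros rather than dividing by zero.
* **Determinism.** All TSV/JSON output uses fixed numeric formatting and
  binary-mode connections, so identical inputs give byte-identical
  bundles; reports are written to a staging directory and renamed into
  place so a failure never leaves a partial bundle.

## The synthetic-structure generator

`gnm_fixture()` writes small, valid PDB files so the whole pipeline is
testable offline: collinear chains (whose contact network at the default
cutoff is exactly the path graph, with the known closed-form spectrum
$4\sin^2(k\pi/2N)$), rings, ideal alpha-helices (rise 1.5 Å, 100° per
residue, radius 2.3 Å — textbook constants), a two-domain dumbbell (two
helical domains joined by an extended 3-node linker, a planted
hinge geometry), a BIOMT dimer (identity plus a rigid translation, or a
proper 2-fold for exact symmetry), an idealized protein–DNA complex
written with complete P/C4'/C2 node atoms, and ellipsoid point clouds of
stated axial ratio. Coordinates are rounded to the PDB column precision
*before* any derived quantity is computed, so a file is always exactly
self-consistent with the B-factors written into it.

The synthetic B-factor model writes $B = c \cdot \mathrm{msf} +
\mathcal N(0, \sigma^2)$ per node, with the profile taken from the
asymmetric unit or from the constructed assembly (the latter plants the
assembly-versus-asymmetric-unit effect: B-factors synthesized from the
dimer network correlate better with the dimer model than with the
monomer). The default scale puts the mean B at 30 Å², a typical
crystallographic magnitude.

What the generator does *not* emulate: real side-chain packing, crystal
contacts, anisotropic or correlated experimental noise, missing residues,
and the heterogeneous contact density of real folds. Passing tests on
fixtures therefore demonstrate the correctness of the machinery — spectra,
pseudo-inverses, selection rules, file round-trips — not the empirical
accuracy of the GNM on real depositions, which is established in the
literature and can be spot-checked by running `gnm_run()` on any
downloaded PDB entry.

Test and verification problem sizes are kept modest by design — chains of
3–50 nodes against closed forms, 50 random geometric graphs up to 200
nodes against a generic pseudo-inverse, 200 seeded noise replicates of a
40-node chain, 50 seeded 30-residue dimers, 20 perturbed dumbbells —
because every property being checked is size-independent and exact
oracles are cheap at these sizes.

## Limitations

* Isotropic GNM only: no directional (3N-dimensional) modes, no mode
  animation vectors.
* PDB text format only; mmCIF-only depositions must be converted first.
* No network access: files are read from disk, never fetched.
* Chain identifiers beyond one character survive in memory but are
  truncated to the PDB column when written.
* For mixed complexes the B-factor comparison uses all nodes with
  experimental values by default; `protein_only_b = TRUE` restricts it to
  protein nodes when nucleotide B-factors are unreliable.
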