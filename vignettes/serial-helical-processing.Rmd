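---
title: "Processing serial helical-scan diffraction from in cellulo crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing serial helical-scan diffraction from in cellulo crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incellproc)
library(dplyr)
```

## The problem

Protein crystals grown inside living insect cells (via baculovirus-driven
overexpression) are micrometre-sized and cannot be mounted individually.
They are measured *in cellulo*: a mesh or film carrying thousands of cells
is scanned through a microfocus beam along serpentine lines while the
goniometer rotates continuously. The result is a serial stream of detector
frames in which most frames are empty, and each crystal appears as a short
contiguous run of diffracting frames — a **wedge** — usable as a tiny
rotation dataset.

`incellproc` implements the computational stages of this pipeline:

1. **Stream handling** — reading, writing, filtering and splitting a
   CrystFEL-like text stream (one *chunk* per frame, each with a spot
   count and zero or more indexed crystals).
2. **Wedge identification and crystal deduplication** — turning per-frame
   spot counts into wedges and merging wedges that are the same physical
   crystal.
3. **Salt-ring filtering** — removing powder-diffraction contamination
   from precipitated salt using resolution-dependent intensity ceilings
   chosen off a *peakogram*.
4. **Monte-Carlo merging** — per-pattern scaling under the "unity"
   partiality model, symmetry reduction, and the serial figures of merit
   Rsplit and CC1/2.
5. **Powder fingerprints** — predicted Debye-Scherrer ring positions in
   s = 4π sin θ/λ for crystal detection by SAXS/XRPD.
6. **Dosing and titration** — TCID50 endpoint-dilution titers and
   MOI-based dosing volumes for the virus work that produces the crystals.
7. **Structure comparison** — Cα superposition and per-residue deviation
   profiles.

A ground-truthed simulator generates every input the pipeline consumes, so
each stage is validated against known answers.

## Wedge identification

The scan is described by a `scan_geometry()`: frames per line, number of
lines, rotation per frame, and the serpentine flag (translation and
rotation invert on odd lines, with the rotation angle resetting at each
line start).

A frame is a candidate **crystal center** when its spot count is a local
maximum within its line (plateaus yield their earliest frame) and reaches
`min_center_count`. Wedges then grow outward from each center while the
spot count stays at or above `min_spots`, never crossing a line boundary,
a frame already claimed by a stronger wedge, or another detected center.
Growth order is descending center count (ties to the lower frame index),
which makes the partition of frames deterministic: when two bumps share a
qualifying frame the stronger center claims it and the weaker wedge stops
one frame short.

Two free parameters matter here and both are exposed rather than hidden:

* `min_center_count` (default 20 spots) — the weakest frame accepted as a
  crystal center; below ~10 the Poisson background (a few spots per empty
  frame) starts producing false centers.
* `min_spots` (default 10 spots) — the weakest frame worth integrating;
  it controls wedge length and hence the rotation range per crystal.

Because a crystal can be hit more than once (adjacent frames, or adjacent
lines when its footprint spans the line pitch), wedges are deduplicated:
wedges that **overlap** and whose unique reciprocal axes agree within
`angle_threshold` (default 6°) are the same crystal; identities are the
connected components of that relation. Non-overlapping wedges are never
merged, however similar their orientation — two aligned crystals in
different places are different crystals.

Overlap has two modes. `"frames"` intersects frame intervals, the literal
reading. `"spatial"` declares overlap when any two member frames sit
within one scan step of each other, which additionally captures (a) the
same crystal hit on two adjacent lines and (b) a single bump split into
two abutting wedges by counting noise. We default to `"frames"` but use
`"spatial"` in the validation studies for exactly those reasons. The
unique axis defaults to c\* for hexagonal, trigonal and tetragonal
lattices and b\* for monoclinic; for lattices without a crystallographic
unique axis the choice is configurable and a warning is emitted.

```{r wedges}
geo <- scan_geometry(frames_per_line = 60, n_lines = 5, rot_per_frame = 0.1)
cell <- unit_cell(90, 90, 170, 90, 90, 120, "hexagonal", "P")
pg <- point_group("6/m")
sim <- simulate_scan(geo, n_crystals = 8, cell, pg, noise_fraction = 0.01,
                     seed = 2, d_min = 25)
fc <- find_crystals(sim$dataset, geo, min_center_count = 20, min_spots = 10,
                    mode = "spatial")
nrow(fc$wedges)
head(fc$manifest)
```

## Stream handling

The stream dialect mirrors the fields the pipeline needs: chunk markers,
image/event identifiers, `num_peaks`, and per crystal the cell (nm in the
file, Å in memory), the reciprocal basis (nm⁻¹), a resolution limit and a
reflection table. Unknown lines inside chunks and crystals are preserved
verbatim and re-emitted, since real streams carry per-facility extras.
Numeric fields are written at fixed precision (cells to 10⁻⁵ nm, basis
vectors to 10⁻⁷ nm⁻¹, intensities to 0.01), and write→read is the
identity at that precision.

`select_chunks()` filters chunks by predicate (the in-memory counterpart
of grep-style stream tools), `split_by_cell()` separates unit-cell
populations — e.g. polymorphs differing only in the c axis — by
first-match-wins comparison against reference cells (5% relative on axes,
1.5° absolute on angles by default), and `split_into_parts()` produces
contiguous equal-chunk parts, the basis of diffraction-power-over-time
monitoring.

## Salt filtering and the peakogram

Diffraction from precipitated salt appears as sharp powder rings: narrow
resolution bands populated by implausibly bright "reflections". The
`peakogram()` — a 2D histogram of 1/d against log10 peak intensity —
makes those bands visible; the user chooses per-band intensity ceilings
from it (an optional helper suggests a per-band quantile, default 0.999).
`filter_salt()` then removes any reflection whose d falls inside a band
and whose **peak value** exceeds the ceiling. Peak height, not integrated
intensity, is the filtered quantity (the bright pixel is the salt
signature); filtering on integrated intensity is available via the
`value` argument. Bands are half-open in d so adjacent bands partition
cleanly, and crystals or chunks emptied by filtering are retained.

## Monte-Carlo merging and figures of merit

Observations are mapped to the asymmetric unit of a merging point group
(operator tables for 1, -1, 2/m, mmm, 4/m, 4/mmm, -3, 6/m, 6/mmm and m-3
are built by closing generator sets; arbitrary groups can be supplied as
generator lists). The orbit representative is the lexicographically
greatest index triple, including Friedel mates for the centrosymmetric
groups.

Per-pattern scaling assumes "unity" partiality — every observation is
treated as a full reflection, and averaging over many random wedges does
the rest. The scale of crystal *j* is estimated by alternating least
squares: merge under current scales, then set
s_j = Σ(I_obs·Ī)/Σ(Ī²) over the crystal's reflections, normalising the
mean scale to 1. Up to `n_rounds` rounds are run (default 3, matching the
one-to-three post-refinement rounds typical of serial merging), stopping
early when the largest relative scale change falls below `tol`; for exact
noise-free validation the round cap can be raised so the iteration runs
to numerical convergence. A crystal sharing no reflection with any other
cannot be scaled and is flagged with scale 1.

Merged intensity is the mean of scaled observations; the merged sigma is
the sample standard deviation over √n, falling back to the observation's
own sigma when n = 1 (singly-observed reflections are common in serial
data and should not be discarded). Halves for Rsplit
(2^(−1/2)·Σ|I₁−I₂| / ½Σ(I₁+I₂)) and CC1/2 (Pearson) are formed by parity
of the chunk frame index — deterministic and close to common practice.
Completeness counts observed unique reflections against a brute-force
enumeration of all indices within the resolution cutoff; shell tables use
equal-volume shells (linear in 1/d³).

```{r merge}
sc <- scale_crystals(sim$dataset, pg, n_rounds = 10)
halves <- merge_halves(sim$dataset, pg, sc)
c(rsplit = rsplit(halves$half1, halves$half2),
  cc_half = cc_half(halves$half1, halves$half2))
glance(shell_stats(sim$dataset, pg, cell, n_shells = 5, d_min = 25))
```

## Powder fingerprints

A unit cell predicts a Debye-Scherrer fingerprint: every lattice plane
family with d ≥ d_min that survives the centering extinction rule (P, A,
B, C, I, F, H) contributes a ring at s = 2π/d (with d in Å and s in nm⁻¹,
s = 20π/d). Rings are grouped at 1e-6 relative in d and weighted by
multiplicity only — ring *positions*, not structure-factor intensities,
are the fingerprint, which is why screw-axis and glide absences (which
remove a few low-order reflections but no positions beyond the centering
set) are not modelled by default. `radial_average()` reduces a detector
image to I(s) using the same s convention, and
`subtract_background_moving_average()` implements the standard treatment
for weak rings on a bright cell-paste background: subtract 90% of a
moving-average background estimate, clipping at zero.
`compare_fingerprints()` scores two fingerprints by greedy
nearest-neighbour matching of ring positions within a tolerance; the
match fraction (matched over the larger ring count) operationalises
whether two crystal forms give "the same" powder pattern.

```{r powder}
fp <- enumerate_rings(cell, d_min = 15)
head(fp, 3)
```

## Dosing and titration

Crystal production starts from a titered virus stock. The endpoint
dilution assay plates a fixed inoculum (20 µL) of serial 1:10 dilutions
into 6 wells per dilution and scores a well positive when it shows at
least two fluorescent (infected) cells. The TCID50 estimator is
Spearman-Kärber: with d the dilution step and S the sum of positive
proportions from the last fully positive row down, the log10 endpoint is
m = x₁₀₀ − d(S − 0.5) and the titer is 10^(−m)/inoculum per mL.
Reed-Muench interpolation is provided behind a method flag since endpoint
spreadsheets in circulation implement either; the method used is recorded
in the result. The dosing volume for a target multiplicity of infection
is `(MOI · cells)/(0.69 · TCID50/mL)`, the factor 0.69 = ln 2 converting
a 50%-endpoint titer into infectious units.

The plate simulator draws infection events per well as
Poisson(0.69 · titer · inoculum · 10^dilution) and renders each event as
a cluster of at least two fluorescent cells, so the ≥2-cell scoring rule
marks exactly the wells with at least one event. Under that model the
Spearman-Kärber estimate is unbiased, which the recovery study (median
log10 error across seeds) confirms.

```{r titer}
plate <- titer_plate(-(2:9), c(6, 6, 6, 6, 3, 0, 0, 0))
tidy(tcid50(plate))
volume_for_moi(moi = 1, cell_number = 1e6, tcid50_per_ml = 5e7)
```

## Structure comparison

`superpose()` performs a least-squares rigid-body Cα superposition
(Kabsch, proper rotation enforced) over residues paired by chain and
residue number. Loop statistics — e.g. the maximum deviation across a
flexible loop — are computed **after the global fit**, not from a local
fit: the question is how far the loop sits from its reference position in
the frame of the whole molecule. When several structures are compared to
one reference, the mean RMSD is the arithmetic mean of the per-structure
global RMSDs. Coordinate files are read through bio3d (PDB and mmCIF; CA
atoms, highest-occupancy altloc, ties to 'A').

## The simulator: what it does and does not emulate

`simulate_scan()` reproduces the *structure* of a helical-scan serial
dataset, not its physics:

* crystals occupy random non-overlapping footprints of 3–15 frames within
  single lines, separated by a 2-frame background margin so neighbouring
  crystals remain resolvable as distinct bumps (physically: distinct
  cells with clear space between them);
* spot counts are a deterministic Gaussian bump per crystal (peak 30–200)
  on a Poisson background of mean 2;
* true intensities are log-normal (sdlog 1), observed through a
  per-crystal scale log-uniform in [0.5, 2] and multiplicative Gaussian
  noise of a chosen fraction; observation indices are emitted as random
  symmetry images of the asymmetric-unit triple;
* orientation is constant within a footprint by default (a flag adds a
  sub-degree per-frame perturbation).

It deliberately omits partiality, mosaicity, detector point-spread and
absorption. Passing tests therefore demonstrate that the *algorithms* are
correct on data with known answers — not that the pipeline's thresholds
are optimal for any particular beamline's data.

## Numerical choices and problem sizes

* Validation studies run at: 2000-frame scans × 20 crystals × 10 seeds
  (wedge recovery); 200 random instances of up to 50 wedges
  (deduplication vs an exhaustive union-find oracle); 100 random
  triclinic cells (ring positions vs the reciprocal-metric-tensor
  oracle); 1000 randomized datasets (stream round trip); 200 plates
  (titer recovery).
* Ring grouping and cell matching tolerances (1e-6 relative; 5% axes /
  1.5° angles) are stated above; merging convergence is 1e-6 relative
  scale change by default.
* Degenerate inputs fail loudly: (0,0,0) has no d-spacing, cells must
  have a positive-definite metric, superposition needs three non-collinear
  pairs, an unbracketed titer plate names the missing side, and a parse
  error reports its line number.

## Known limitations

* The stream dialect is a documented subset; geometry files, HDF5 image
  payloads and every historical stream variant are out of scope.
* Partiality models beyond "unity", push-res semantics, and MTZ output
  belong to the external tools this package sits beside.
* Salt thresholds are chosen by the user from the peakogram; no automatic
  fit is attempted beyond the quantile helper.
* Powder intensities ignore structure factors and Lorentz-polarization;
  only ring positions and multiplicities are meaningful.
* The titration module estimates endpoint titers; growth-curve modelling
  of amplification time courses is not attempted.
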