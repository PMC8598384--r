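---
title: "Measuring root morphology from scans: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring root morphology from scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootquant)
```

## The measurement model

`rootquant` measures washed roots from high-contrast scans. Its unit of
analysis is an 8-bit greyscale raster: colour scans keep only their red
channel (the channel with the most root/background contrast under a
transparency unit) and 16-bit scans are reduced by integer division by
257, so full scale maps to full scale. Coordinates are 0-based with the
origin at the top-left and y growing downward; "depth" therefore grows
with the row index, matching scanner raster order and the orientation of
root-crown images.

Segmentation is deliberately simple — a global threshold — because the
imaging protocol (scanner with transparency unit, or a backlight for
crowns) is expected to deliver the contrast. Everything downstream assumes
only a binary mask, so masks from external segmentation tools can be fed
in as images too. Root components and background components both use
8-connectivity. That choice decides a classic boundary case: a single
bright pixel inside a root that touches a background pixel diagonally is
*connected* to the outer background and is not a hole, so hole filling
leaves it alone. Filtering order is fixed and documented: threshold, then
background component-size filter, then hole filling, then optional
contour smoothing.

## The radius-annotated medial axis

The skeleton is built from an exact Euclidean distance transform (EDT):
each root pixel's distance to the nearest background pixel centre, which
on the medial axis is the local root radius in pixels. Ridges of the EDT
seed the skeleton: a pixel qualifies when its value dominates both
neighbours of at least one opposite-direction pair.

Tie handling is where discrete geometry bites, and the exact rules are
package design choices:

* **Axis pairs (E/W, N/S)** accept any strict two-sided maximum, or a tie
  with one neighbour while beating the opposite one by a full pixel. The
  full-pixel clause is the signature of an even-width root: its EDT
  plateau is two pixels wide, the two plateau rows tie, and the flanks sit
  exactly 1 px lower. Fractional-excess ties also occur in numbers along
  curved boundaries (EDT values are square roots of integers and tie
  accidentally), and accepting them seeds concentric arcs of false ridge
  pixels; requiring integer excess rejects them while keeping genuine
  plateaus and the small-excess strict maxima that carry the axis through
  rounded root tips.
* **Diagonal pairs (NE/SW, NW/SE)** require at least half a pixel of
  excess on both sides. A genuine diagonal ridge — a corner bisector —
  dominates its cross-diagonal neighbours by about 1 px, while the parity
  fluctuations of the exact EDT along curved boundaries stay below 0.5 px
  and would otherwise produce checkerboard webs.

Ridges on a lateral root stop short of a thicker parent's ridge because
the EDT keeps climbing across the junction. Each ridge fragment is
therefore walked uphill from its endpoints (ties broken in the fixed
order E, NE, N, NW, W, SW, S, SE; plateaus may be crossed), until the walk
reaches — or lands next to — existing skeleton, or stalls. Connections
form a forest over fragments: a walk that would join two fragments that
are already connected is discarded, so connection itself never creates a
cycle; stalled walks are discarded for the same reason. If fragments
remain detached (degenerate plateaus), a deterministic breadth-first
bridge through the mask restores the invariant that each mask component
carries exactly one skeleton component. Components with no ridge at all
(tiny blobs) are seeded with their EDT maximum.

Guo–Hall two-subiteration thinning then reduces the (at most two-pixel
wide) structure to one-pixel width while preserving connectivity. Two
conservative clean-ups follow: any pixel completing a fully occupied 2×2
block is deleted when its neighbourhood remains connected (a simple-point
test), and "redundant corners" — a degree-2 pixel whose two neighbours
are mutually adjacent, or a degree-3 pixel resting on three consecutive
collinear pixels — are collapsed. Corner collapse also removes staircase
L-corners, which matters for length: the length sum counts every skeleton
adjacency once, and an L-corner would add a spurious diagonal shortcut.

### False loops

The medial axis of a simply connected region is a tree, but discrete
ridge geometry can produce cycles that enclose no background — crossing
bisector chains near rounded root ends are the typical source, and such
false loops are a recognised artifact of skeleton-based root analysis.
`rootquant` resolves them with an explicit rule: a skeleton cycle whose
interior contains no background pixel is broken at its lowest-radius
degree-2 pixel (falling back to any simple point on the cycle, ties by
position). Cycles that do enclose background — crossing roots, annular
shapes — are genuine and kept; the suppression triggers only while the
skeleton has more independent cycles than the mask has holes. Because the
cross-links of a loop also act as junctions that pruning can exploit,
suppression runs alternately with pruning rather than before it.

## Topology and pruning

Skeleton pixels are classified by neighbour count: tips (at most one
neighbour; an isolated pixel is a degenerate tip contributing zero
length), branch points (three or more) and segment pixels (exactly two).
Segments are traced between endpoint pixels; pure cycles are reported as
closed loop segments.

Root pruning deletes invalid laterals: every branch-to-tip segment whose
path length (branch pixel centre to tip pixel centre, the
branch-to-first-pixel step included) is at most the branch pixel's radius
plus a margin (default 5 px) is removed, iteratively, until stable.
Candidates are processed in ascending length-minus-radius order with ties
broken by branch position, which makes the cascade deterministic.
Segments joining two branch points are never deleted, free tip-to-tip
components are never deleted, and the segmented mask is never altered —
pruning is a skeleton-only operation. Internally deletions are batched
per pass for speed, but a pass stops at the first candidate whose
surroundings were touched by an earlier deletion (or whose branch merged),
so the realised sequence is identical to deleting one segment at a time;
the test suite asserts that equality against a one-deletion-at-a-time
oracle on random skeletons.

## Traits

All traits derive from the mask, the pruned skeleton and its radii:

* length: sum of skeleton adjacency steps (1 orthogonal, √2 diagonal);
* diameters: twice the radius per skeleton pixel; average, median,
  maximum, unweighted across pixels (a length-weighted average is
  available as an option but off by default);
* network area: root pixel count; perimeter: Euclidean step sum along
  traced outer and inner contours;
* surface area and volume: per-pixel cylinders of radius `r(p)` and
  height `h(p)` = half the summed distance to skeleton neighbours, so
  heights sum exactly to total length. Per-diameter-bin histograms
  (length, projected area `h·2r`, surface area, volume) use
  left-open/right-closed ranges and sum exactly to the unbinned totals;
* whole-root mode adds crown extent (inclusive bounding-box spans),
  convex area and solidity, per-scan-line root counts (median and maximum
  of background-to-root transitions), the network area below the
  thickest skeleton pixel, hole count and mean size, and angle features.

Angle features use, for every skeleton pixel, the principal axis of the
skeleton coordinates inside its 40×40 locality, expressed as the absolute
angle from vertical: 0° is plumb (steep), 90° horizontal (shallow), with
frequency bins [0°, 30°), [30°, 60°), [60°, 90°]. Frequencies are
reported as fractions of skeleton pixels (not raw counts) so they sum to
one. The vertical reference matches root-crown gravitropism — steep
means downward growth.

Two open conventions were fixed as follows: the convex hull raster is the
set of pixel centres inside or on the hull polygon, with the hull edges
rasterized in, so a degenerate collinear point set yields the digital
segment through the points and solidity stays in (0, 1]; the perimeter
follows traced contour pixels (not the crack boundary), counting both the
outer boundary and one inner contour per enclosed hole.

Empty results are a policy, not an error: an empty segmentation produces
a record of zeros with a warning, so batch runs always complete.

## Units, files, batch

Resolution may be given as DPI (divided by 25.4) or pixels per mm, or
read from PNG/TIFF/BMP metadata; without it, traits are reported in pixel
units and the mm columns are `NA`. Component/hole sizes and diameter bin
edges are interpreted in mm-based units exactly when a resolution is
known. Settings round-trip through a `key,value` CSV with documented
defaults (broken-roots mode, threshold 128, all optional filters off,
pruning margin 5 px); regions of interest round-trip through a versioned
one-line-per-ROI text format. Compatibility with other tools' settings or
ROI dialects is not promised. Batch runs are lexicographic and
fault-tolerant: per-file failures are logged and skipped.

## The synthetic scenes and what they show

The generator renders dark elongated objects of controlled integer stroke
width on a bright background: straight wires with square-cut ends (as
pliers leave on copper wire), arc wires with round caps, and branched
root phantoms with laterals. Ground truth is computed from the *rendered*
geometry — integer width, pixel path length — so recovery tests measure
algorithm error, not rasterization error. Seeded corruption adds
background speckles and in-root bright holes with clearances chosen so
that size-capped filtering restores the clean segmentation exactly.

The default validation scenes emulate 600 DPI scans of cut copper wires,
one wire per gauge of the AWG 40/32/28/22/16/10 ladder (rendered widths
about 2–61 px), laid side by side, with seeded per-wire lengths of
100–140 mm providing the across-scene variation. Two scale choices are
worth stating. First, flat wire ends: hemispherical caps of radius R
carry radial medial branches of length R√2, which exceeds the pruning
cutoff R + 5 for R above ~12 px, so round-capped thick objects retain a
few percent of end-artifact length under the standard 5 px margin —
square-cut ends bound the artifact to four short corner spurs, and are
also what cut wire actually looks like. Second, wire length: end
artifacts are a constant per wire, so the package's choice of ~120 mm
wires makes relative length error *larger* than it would be for
longer wires; accuracy figures at this scale are conservative.

What passing these tests does *not* show: the scenes have crisp,
noise-free boundaries, no glare or blur, no antialiasing, no root hairs
and no overlapping objects. Real scans are kinder in some respects
(boundary noise breaks up the degenerate symmetric artifacts of perfect
rasters) and harsher in others (hairs, debris, touching roots inflate
every trait). The validation quantifies the measurement core, not image
quality.

## Numerical notes and limitations

* All tie-breaks (walk order, pruning order, loop-break position) are
  fixed and documented, so results are bit-reproducible for a given
  input; generator fixtures are additionally seeded.
* EDT radii are distances to background pixel *centres*, so a bar of odd
  width w has axis radius (w+1)/2: diameters carry up to +1 px bias and,
  for thin odd-width roots, volume inherits the squared effect. This is a
  property of the radius definition, visible in the per-width accuracy
  tests, and averages out across mixed-width samples.
* On even-width straight stretches the thinned axis sits half a pixel off
  the true centre (the plateau has no middle pixel); lengths are
  unaffected.
* Pruning cannot remove branch-to-branch segments by design, and the
  radius-plus-margin rule provably retains medial branches longer than
  the local radius plus the margin — e.g. the corner spurs of wide flat
  ends. Raising the margin trades those against real short laterals.
* Root-order classification (lateral versus axial), per-root
  measurements, root-hair handling and machine-learning segmentation are
  out of scope; segmented masks from external tools can be analysed
  directly.
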