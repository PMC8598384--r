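# rootquant

Measurement of plant root morphology from high-contrast scans of washed
roots — the kind produced by a flatbed scanner with a transparency unit.
`rootquant` is aimed at root biologists and phenotyping labs who need
reliable length, diameter, surface-area and volume estimates for washed
root fragments (soil cores, pots) or whole root crowns, in batch, with
ground-truth validation machinery built in.

## The method

Roots are darker than the scanner background, so a pixel is root when its
8-bit intensity is at or below a global threshold *t* (inverted for backlit
crowns). Small non-root components (soil debris) up to a user area are
erased, enclosed bright holes up to a user area are filled, and contours
can optionally be simplified with the Ramer–Douglas–Peucker rule.

The core of the package is a radius-annotated medial axis:

1. an **exact Euclidean distance transform** *D* gives every root pixel its
   distance to the nearest background pixel — on the medial axis this is
   the local root radius *r*;
2. **ridge detection** keeps pixels whose *D* value dominates both
   neighbours of an opposite-direction pair (E/W, N/S, NE/SW, NW/SE);
3. detached ridge fragments (laterals whose ridge dies on the flank of a
   thicker parent) are joined by **steepest-ascent walks** on *D*;
4. **Guo–Hall thinning** reduces the result to a one-pixel-wide skeleton
   that preserves connectivity.

Skeleton pixels are classified by neighbour count — tip (≤ 1), branch
point (≥ 3), segment (2) — and **root pruning** iteratively deletes every
branch-to-tip segment not longer than the branch radius plus a user margin
(default 5 px): an invalid lateral born of boundary roughness is never
longer than its parent's radius.

Traits follow from per-pixel geometry. Total length is the sum of skeleton
adjacency steps (1 orthogonal, √2 diagonal). Every skeleton pixel is
treated as a cylinder of radius *r(p)* and height *h(p)* (half the summed
distance to its skeleton neighbours, so Σh equals total length):

    volume       = Σ h(p) · π · r(p)²
    surface area = Σ h(p) · 2π · r(p)

Summing cylinders per pixel — rather than applying the average diameter to
the total length — is what keeps volume honest when fine laterals and
coarse axes share an image; the average-diameter shortcut can miss half
the volume. Length, projected area, surface area and volume are also
reported per user-defined diameter bin, and whole-root mode adds crown
extent, convex hull and solidity, holes, per-scan-line root counts and
angle frequencies. Accuracy against ground truth is quantified by MBE,
RMSE and R² (squared Pearson).

## A worked example

Synthetic scenes with analytic truth are built in, so the pipeline can be
exercised without any scanner:

```r
library(rootquant)

scene <- renderWires(list(wireSpec(diameter_mm = 0.2, length_mm = 100,
                                   position = c(20.5, 1190)),
                          wireSpec(diameter_mm = 2,   length_mm = 100,
                                   position = c(80.5, 1190))),
                     pxPerMm = 600 / 25.4)

cfg <- analysisConfig(thresholdLevel = 191, filterBackground = TRUE,
                      maxComponentSize = 8, pruningEnabled = TRUE,
                      pruningThresholdPx = 5, dpi = 600)
rec <- extractFeatures(scene$image, cfg)

rec$total_length_mm        # 203.49   (truth 199.98)
rec$avg_diameter_mm        # 1.049    (length-weighted truth 1.101)
rec$volume_mm3             # 300.3    (truth 314.4, -4.5%)
pi * (rec$avg_diameter_mm / 2)^2 * rec$total_length_mm
                           # 175.8 -- the average-diameter shortcut
                           #          misses 44% of the volume
```

The numbers above are what the code prints for this scene: the per-pixel
cylinder volume lands within 5% of truth while the length × average-diameter
estimate collapses, because the thick wire carries almost all the volume
and the thin wire drags the average diameter down.

For real scans: `loadImage()` reads PNG/JPEG/BMP/TIFF (red channel of
colour images, 16-bit rescaled), `runSingle()` analyses one image with
optional named regions of interest, and `runBatch()` processes a folder
into `features.csv` plus a `metadata.csv` of the exact settings used. A
command-line wrapper lives at `inst/scripts/rootquant-analyze.R`.

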