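# svcnet

Simulation of how **spatial view cells** — hippocampal-system neurons that
fire when a particular location in a viewed scene is fixated — can be built
by a biologically plausible hierarchy in the primate ventromedial visual
"scene" pathway, and how their fixation-patch representations are stitched
into a **whole-scene map** by gaze-direction gain modulation and a
continuous attractor.

The package is for computational neuroscientists who want a tested,
reproducible implementation of this class of model: competitive
feature-hierarchy learning over a Gabor front end, sparseness-constrained
threshold-linear competition, memory-trace learning, coordinate remapping
by gaze, and distance-weighted associative recurrent weights — plus
synthetic stimuli, receptive-field mapping, and a small CLI.

## The model in brief

A 256×256 fixation-patch image is encoded by a V1-like bank of Gabor
filters (4 octave-spaced frequencies × 4 orientations × 2 signs = 32
half-rectified channels). Three 32×32 layers follow, each receiving a fixed
number of afferents (54, 40, 40) drawn from a radial Gaussian of radius
1 / 1.7 / 1.7 centred on the topologically aligned position — the radius
contains ≈ 67% of the connections. Activations are inner products
`h_i = Σ_j w_j x_j`; lateral inhibition is a zero-sum difference of
Gaussians (radii 0.2/1.5); the threshold is set so the population
sparseness

    a = (Σ_i y_i / n)² / (Σ_i y_i² / n)

reaches each layer's target (0.1, 0.12, 0.08). Learning is associative,
`δw_j = α y x_j`, or uses the short-term memory trace
`ȳ^τ = (1−η) y^τ + η ȳ^{τ−1}` (`δw_j = α ȳ^τ x_j`, η typically 0.8), with
weight vectors renormalised to unit norm. In Layer 3 a gaze direction
places the (half-sized) patch representation into one quadrant of a ±70°
scene frame, and recurrent weights grow between co-active neurons as
`δw_ij = α y_i y_j exp(−d_ij²/2σ_d²)`, forming a continuous attractor whose
activity bump moves under firing-rate adaptation.

## Worked example

Train on the two alphanumeric demonstration patches (digits 1–9 at gaze
upper-left, letters A–I at upper-right), then inspect the layers:

```r
library(svcnet)

scene <- demo_scene_alphanumeric()
model <- build_model(config_alphanumeric_demo(), seed = 1)
model <- train(model, scene, training_schedule(seed = 1))   # 7 epochs

out_ul <- present(model, scene$patches$UL, "UL")
out_ur <- present(model, scene$patches$UR, "UR")

sum(out_ul$y1 > 0)            # 142  -- Layer-1 neurons active for the digits
out_ul$detail[[1]]$a          # 0.1  -- Layer-1 sparseness at its target

act <- which(out_ul$y3 > 0, arr.ind = TRUE)
nrow(act)                     # 91   -- scene-layer neurons active
sum(act[,1] <= 16 & act[,2] <= 16)  # 89 of 91 sit in the upper-left quadrant

nrn <- which.max(as.numeric(out_ul$y3) - as.numeric(out_ur$y3))
out_ul$y3[nrn]                # 7.19 -- a spatial view cell's rate to its patch
out_ur$y3[nrn]                # 0    -- and to the other patch
selectivity_index(out_ul$y3[nrn], out_ur$y3[nrn])   # 1
```

The active Layer-1 populations for the two patches overlap by 48% of the
smaller set — different glyphs recruit different feature-combination
neurons — and the Layer-3 support lands in the quadrant selected by gaze:
each such neuron is a spatial view cell for one part of the whole scene.

Receptive fields are mapped by moving a 32×32 probe in 2-px steps over the
image (a 113×113 response lattice):

```r
rf <- map_receptive_field(model, scene$patches$UL, layer = 3, neuron = nrn,
                          gaze = "UL")      # step = 2 by default
rf_size(rf)$diameter_deg                    # half-max RF diameter in degrees
```

The continuous attractor can be demonstrated by relaxing a cue into a bump
and switching on adaptation (`bump_dynamics`), which makes the bump travel
semi-continuously across the trained part of the scene map.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/svcnet.R gen-stimuli --out stimuli --seed 1
Rscript inst/cli/svcnet.R train --out model --seed 1
Rscript inst/cli/svcnet.R map-rf --model model --out rf --layer 3
Rscript inst/cli/svcnet.R demo-bump --model model --out bump
```

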