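# nervect

Anatomy-aware 3D segmentation of peripheral nerve microCT in R.

Contrast-stained microCT resolves the internal architecture of peripheral
nerves — bright **fascicles** (fiber bundles) inside mid-intensity
**epineurium** (connective sheath) against dark background — at ~11 µm
isotropic voxel spacing. In plexiform nerves such as the human vagus,
fascicles repeatedly **split and merge** along the longitudinal axis, and
mapping that morphology requires segmentations that are not just
voxel-accurate but *anatomically coherent*. `nervect` is for researchers who
need such segmentations and, just as much, for those who need to **evaluate**
them with anatomy-aware criteria.

The package provides:

* a three-class 3D U-Net (background / fascicle / epineurium) trained with
  the compound loss

  L = L<sub>CE</sub> + L<sub>Dice</sub> + λ·L<sub>Topo</sub>,&emsp;
  L<sub>Topo</sub> = CE(p ⊙ V, g ⊙ V)

  where the **critical voxel map** V flags every voxel violating the
  anatomical constraints — *fascicles must be completely enclosed by
  epineurium* and *cannot directly contact background* — detected as
  26-adjacent fascicle/background pairs in the hard prediction (λ = 10⁶ at
  the full 32×256×256 patch; `scaled_loss_config()` preserves the per-voxel
  weight at desk-scale patches);
* the full training recipe (33% foreground-guaranteed patch sampling,
  intensity clipping to [0, 32767] and rescaling, rotation/noise/contrast
  augmentation, SGD + Nesterov 0.99, poly learning-rate decay
  lr₀(1−e/e_max)^0.9, patch-based in-training validation) with the
  forward/backward passes written from scratch in Rcpp — no deep-learning
  framework required;
* sliding-window inference with 25% overlap and Gaussian-weighted blending
  (σ = 0.125 of the patch edge);
* a synthetic **plexiform-nerve phantom generator** with a known split/merge
  event ledger, used as training corpus and metric ground truth;
* standard metrics — Dice (DSC = 2|P∩G|/(|P|+|G|)), surface Dice at
  tolerance τ, average symmetric surface distance (µm), IoU / sensitivity /
  specificity — and anatomy-aware ones: per-slice fascicle instance F1 over
  IoU thresholds 0.50–0.95, over-/under-segmentation and size-stratified
  miss rates (tiny/small/medium/large bins at 0.02/0.09/0.3 mm²), centerline
  Dice (clDice) over 3D skeletons, anatomical error rate, inter-slice
  boundary (BF) consistency, and split/merge event-rate deviation
  (|ΔR_split| + |ΔR_merge|)/2 in events per mm;
* TIFF-stack and OME-Zarr I/O and a command-line tool
  (`exec/nervect`) with `phantom`, `train`, `predict` and `evaluate`
  subcommands.

## Worked example

Generate a phantom, track its split/merge events, then score a degraded
prediction (every fascicle eroded by its one-pixel contour) against the
ground truth:

```r
library(nervect)

spec <- phantom_spec(n_splits = 2, n_merges = 1, n_fascicles_initial = 8,
                     fascicle_radius_range_um = c(30, 80), seed = 7)
ph <- generate_phantom(spec)
ph
#> <phantom_truth> 32 x 128 x 128; 10 fascicle tracks, 2 splits, 1 merges (seed 7)
ph$events
#> # A tibble: 3 × 4
#>   kind  z_index parents children
#>   <chr>   <int> <chr>   <chr>
#> 1 split       5 f1      f1,f9
#> 2 split      15 f8      f8,f10
#> 3 merge      27 f4,f3   f4

detect_split_merge_events(ph$labels)
#> <event_track> 2 splits, 1 merges over 0.365 mm (5.48, 2.74 events/mm)

interior <- function(m) {           # pixels whose 4-neighborhood is inside m
  up <- rbind(FALSE, m[-nrow(m), ]); down <- rbind(m[-1, ], FALSE)
  left <- cbind(FALSE, m[, -ncol(m)]); right <- cbind(m[, -1], FALSE)
  m & up & down & left & right
}
pred <- ph$labels$labels            # erode each fascicle by its contour ring
for (z in seq_len(dim(pred)[1])) {
  f <- pred[z, , ] == 1L
  pred[z, , ][f & !interior(f)] <- 2L
}
evaluate_segmentation(label_volume(pred), ph$labels)
#> <nervect_eval>
#>   fascicle:   DSC 0.8179  surface DSC 0.9922  ASSD 8.381 um  clDice 0.5019
#>   epineurium: DSC 0.9855  surface DSC 0.9961  ASSD 2.666 um
#>   anatomical error rate 0; BF fascicle 0.8819; mean F1@0.5 0.9250
#>   events: pred 2/1 vs gt 2/1 (split/merge); rate deviation 0 /mm
```

Reading the output: eroding a one-pixel ring costs thin fascicles a lot of
volumetric overlap (fascicle DSC 0.82) and clDice (0.50 — centerlines of the
thinnest fascicles fall outside the eroded masks) while the surfaces stay
within one voxel (surface DSC 0.99, ASSD 8.4 µm ≈ 0.7 voxel), no anatomical
constraint is violated (error rate 0), and all three split/merge events are
still recovered (rate deviation 0).

Training and prediction at desk scale:

```r
phs  <- lapply(1:5, function(s) generate_phantom(phantom_spec(seed = s)))
arch <- scaled_arch_config()
tc   <- scaled_training_config(seed = 1)
m    <- train_model(phs[1:3], phs[4], arch, tc,
                    augmentation_config(), scaled_loss_config(tc$patch_size))
out  <- predict_volume(phs[[5]]$image, m)
tidy(evaluate_segmentation(out$labels, phs[[5]]$labels))
```

The same steps are available from a shell:

```sh
exec/nervect phantom --seed 7 --shape 32,128,128 --splits 2 --merges 1 \
  --out-image img.tif --out-labels gt.tif --out-events events.csv
exec/nervect evaluate --pred seg.tif --truth gt.tif --spacing-um 11.4 \
  --report report.json
```

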