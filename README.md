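# panelmae

Channel-wise masked-autoencoder imputation and greedy marker-panel
selection for multiplexed tissue imaging, in R.

## The problem

Multiplexed tissue imaging (MTI) platforms such as cyclic
immunofluorescence (CyCIF) measure dozens of protein markers on one
tissue section by repeated stain/image/bleach cycles.  Every cycle adds
cost, acquisition time and tissue damage, so the *measured* panel is
precious.  Much of a large panel is statistically redundant: marker
co-expression and cell morphology let a model predict many channels from
a well-chosen subset.

`panelmae` implements that idea end to end:

1. **Channel-wise masked autoencoder.**  Each segmented cell is a
   `32 x 32` crop with `C` marker channels.  The `C` channels are laid
   out as tiles of a `g x g` mosaic (`g = ceiling(sqrt(C))`; 25 channels
   give a 160 x 160 single-channel image), so one vision-transformer
   patch is exactly one marker.  During self-supervised training a fixed
   fraction of channels per cell is hidden; the ViT encoder sees only the
   surviving tiles, a learned mask token stands in for hidden ones at the
   decoder input, and the ViT decoder in-paints them.  The loss is mean
   squared error on the masked tiles only.  After training, "masking" a
   marker means *not measuring it*: the model imputes any held-out
   channel subset from a measured reduced panel.

2. **Iterative greedy panel selection.**  With the trained imputer
   `f(X; theta)`, markers are ordered by predictive value:

   `Panel_1 = {DAPI}`,
   `Panel_k = Panel_{k-1} U { argmax_c  mean-rho(Y, f(X, Panel_{k-1} U {c})) }`

   where at each step the held-out set `Y` is the complement of the
   candidate panel and `rho` is the Spearman correlation between actual
   and predicted per-cell mean intensities.  The result is a nested
   marker ordering with per-step held-out scores.

3. **Preprocessing** (16-to-8-bit percentile rescaling, core-level QC at
   2 SD on channel means, histogram matching against reference cores,
   moment-based single-cell pose alignment, cell-level 90/5/5 and
   core-level k-fold splits), **evaluation** (per-marker Spearman /
   Pearson / SSIM, correlation variance across stains, core-level
   cross-validation) and a **synthetic single-cell generator** with known
   latent-factor ground truth so the whole stack is testable without real
   imaging data or GPUs.

## Worked example

```r
library(panelmae)

# 2000 synthetic cells, 6 markers, rank-2 latent structure: DAPI carries
# factor 1, CD45 factor 2, every other marker mixes both.
sim    <- generate_stack(synthetic_spec(n_cells = 2000, seed = 11, noise_sd = 0))
splits <- split_dataset(sim$stack, c(0.9, 0.05, 0.05), seed = 2)

cfg <- mae_config(enc_embed_dim = 32, dec_embed_dim = 16, heads = 2,
                  layers = 2, mlp_dim = 128, train_mask_ratio = 0.5,
                  epochs = 30, batch_size = 32, learning_rate = 2e-3,
                  seed = 5)
model <- channel_mae(splits$train, cfg)
model
#> <channel_mae> 6 channels, enc 32 / dec 16 dims, 2 heads, 2 layers
#>   trained 30 epochs on 1800 cells; final masked-tile MSE 0.00059
#>   markers: DAPI, CD45, PanCK, CD3, Ki67, ECad

# measure a 3-marker reduced panel; impute the other three markers
report <- evaluate_panel(model, splits$test, c("DAPI", "CD45", "PanCK"))
report
#> <eval_report> split 'test': panel of 3 markers, 3 held out, 100 cells
#>   mean Spearman rho 0.9242 (variance across stains 0.0009), mean SSIM 0.9238
#>  marker spearman pearson  ssim
#>     CD3    0.892   0.898 0.885
#>    Ki67    0.928   0.932 0.915
#>    ECad    0.952   0.960 0.971

# order markers by predictive value on the selection split
select_panel(model, splits$val, max_k = 4)
#> <panel_trajectory>
#>  step marker mean_rho
#>     1   DAPI   0.0855
#>     2   Ki67   0.9017
#>     3    CD3   0.9647
#>     4   ECad   0.8955
```

The per-step `mean_rho` is the average held-out Spearman correlation:
with DAPI alone (which carries only the first latent factor) the
remaining five markers are essentially unpredictable; adding one
second-factor-heavy marker (here Ki67 — with this loading several
markers span the missing factor equally well) closes the latent space
and the score jumps to 0.90, after which further markers refine it.
`evaluate_panel`'s per-marker table shows the same at a fixed panel:
every imputed marker's per-cell mean intensity correlates strongly with
truth, and the SSIM column confirms the predicted *images* (not just
their means) resemble the real channels.

An end-to-end run (simulate, split, train, select, evaluate, with every
artifact stamped by a configuration hash) is:

```r
run_pipeline(run_config(seed = 1), "out/")
```

and a thin CLI over the same functions lives at
`inst/cli/panelmae.R` (subcommands `simulate`, `train`, `select-panel`,
`impute`, `evaluate`, `crossvalidate`, `run-all`).

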