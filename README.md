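# fruitcam

Explainable-CNN-guided tissue sampling, tested end to end on synthetic data
with planted ground truth.

## The problem

Some disorders of harvested fruit — the motivating case is rapid
over-softening of persimmon — develop days after harvest while the fruit
looks normal on the shelf and at the packing line. A convolutional network
can nevertheless predict the fate from an RGB photograph of the fruit apex,
which implies the image contains subtle premonitory symptoms. That opens a
workflow biologists can act on:

1. train a binary CNN (rapid-softening vs control) on apex photographs;
2. localise the image regions that carry the prediction with Grad-CAM /
   guided Grad-CAM, at a convolutional layer shallow enough that the
   relevance grid resolves a sampling window;
3. summarise where relevance accumulates via the histogram *H*(*r*, *d*) of
   per-pixel relevance weight *r* against normalized contour distance *d*
   (*d* = 0 at the fruit outline, 1 at the centre);
4. cut tissue from the *featured* region of predicted rapid-softening
   fruits (RS-F), the *non-featured* region of the same fruits (RS-NF), and
   the featured region of predicted controls (C-F);
5. compare transcriptomes under two criteria: (i) RS-F vs C-F, unpaired
   across fruits (DESeq2 Wald, *P* < 0.05, RPKM > 1), and (ii) RS-F vs
   RS-NF, paired within fruit (edgeR with a fruit blocking factor,
   FDR < 0.1, RPKM > 1).

fruitcam implements every stage of that loop — including the CNN itself,
written in R with full forward/backward passes so the explainability code
has direct access to activations and modified ReLU gradients — and wraps it
around two synthetic generators with planted ground truth: fruit-like
images whose class signal is carried only by low-amplitude blemishes at
controlled contour distances, and paired negative-binomial count matrices
with planted differentially expressed genes. Because the truth is planted,
localisation and recovery are measurable quantities, not anecdotes.

## Worked example

Train a model on synthetic fruit with apically planted blemishes, explain
its predictions, and recover the planted geometry:

```r
library(fruitcam)

cfg  <- scene_config(image_side = 48, blemish_amplitude = 0.3,
                     blemish_placement = data.frame(lo = 0.75, hi = 1, weight = 1))
ds   <- generate_dataset(cfg, n_pos = 100, n_neg = 100, seed = 11)
sp   <- split_train_val(ds, ratio = 3, seed = 1)
spec <- model_spec(input_side = 48, block_widths = c(6, 12, 24))
m    <- train_classifier(sp$train, sp$val, spec,
                         train_config(epochs = 80, batch_size = 8,
                                      momentum = 0.95, seed = 1))

glance(evaluate_predictions(predict(m, sp$val)))
#> # A tibble: 1 x 5
#>     auc accuracy positive_precision negative_precision     n
#>   <dbl>    <dbl>              <dbl>              <dbl> <int>
#> 1     1        1                  1                  1    50

pos  <- sp$val[sapply(sp$val, `[[`, "label") == "positive"]
maps  <- lapply(pos, function(i) guided_grad_cam(m, i, layer_name = "conv_shallow"))
dmaps <- lapply(pos, function(i) normalized_contour_distance(segment_fruit(i)))
band_relevance_summary(relevance_histogram(maps, dmaps))
#> # A tibble: 3 x 7
#>   band       d_lo  d_hi  mass mass_fraction pixel_fraction enrichment
#>   <chr>     <dbl> <dbl> <dbl>         <dbl>          <dbl>      <dbl>
#> 1 periphery  0     0.1      0        0              0.138      0
#> 2 mid        0.1   0.75     1        0.0238         0.788      0.0302
#> 3 apex       0.75  1       41        0.976          0.0734    13.3
```

The classifier separates the held-out set perfectly, and the
high-relevance mass of *H*(*r*, *d*) is enriched 13-fold in the apex band
(*d* in [0.75, 1]) — exactly where the blemishes were planted. Re-running with peripherally planted blemishes
(`lo = 0, hi = 0.1`) moves the enrichment to the periphery band.

The full loop — two camera models, ensemble selection, region extraction,
count simulation and the two-criteria comparison — runs from one call:

```r
run <- run_pipeline(pipeline_config(), output_dir = "run1", seed = 1)
report(run)$summary
```

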