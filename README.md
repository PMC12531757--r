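# cardiochip

Quantification toolkit for vascularized heart-on-a-chip imaging: calcium
transients, microvascular morphology, vascular permeability and liposome
extravasation — with seeded synthetic-data generators so every analysis is
validated by parameter recovery.

## Who this is for

Labs running cardiac microphysiological systems (engineered myocardium with
a perfusable microvascular network) collect four recurring kinds of imaging
data:

1. **GCaMP calcium movies** of spontaneously beating cardiomyocytes
   (30 s at 10 ms frame interval),
2. **CD31 confocal z-stacks** of the microvascular network,
3. **tracer time-lapse frames** (e.g. 70 kDa dextran at 0, 3, 6, 9, 12 min)
   for vascular permeability,
4. **liposome / vessel channel pairs** for nanoparticle extravasation.

`cardiochip` implements the corresponding quantification pipelines as
plain R functions with tibble outputs, so results slot directly into a
dplyr/ggplot2 workflow.

## The quantities at the core

**Calcium transients.** Per ROI, the raw fluorescence trace is normalized
to ΔF/F₀ = (F − F₀)/F₀ (F₀ = 10th percentile of the trace by default).
Beats are detected as prominent peaks; each beat *i* is parameterized by
its amplitude *Aᵢ* (peak minus local baseline), time to peak (onset at the
10 % amplitude crossing), and time to 80 % decay. With inter-beat
intervals IBIᵢ between consecutive peaks, the summary statistics are

- frequency  f = 1 / mean(IBI),
- CV of frequency = sd(1/IBIᵢ) / mean(1/IBIᵢ),
- mean amplitude and CV of amplitude = sd(Aᵢ)/mean(Aᵢ),

where the two CVs (sd/mean, sample sd) serve as arrhythmia indices.
Longitudinal recordings are expressed as fold changes against each chip's
day-0 baseline (`normalize_to_day0()`).

**Vessel morphometry.** Maximum projection → Gaussian blur (σ = 2 px) →
triangle threshold → binary erosion → despeckle → Zhang–Suen
skeletonization. From the mask and its skeleton:

- vessel area fraction = foreground / field,
- total network length L (skeleton steps: 1 px orthogonal, √2 diagonal),
- mean diameter d = vessel area / L,
- connectivity = junctions / endpoints (junction: skeleton pixel with ≥ 3
  neighbours, adjacent junction pixels merged; endpoint: exactly 1).

**Permeability.** With tissue intensity I_t(t) rising linearly during
tracer influx, the apparent permeability of a cylindrical vessel of
diameter d is

    P = (dI_t/dt) / (I_v − I_b) × d/4        [cm s⁻¹]

estimated by least squares over all frames.

**Extravasation.** The extravascular fraction is the proportion of
liposome-positive pixels outside the (optionally dilated) vessel mask.

**Statistics.** `compare_to_control()` reproduces the normality-gated
workflow: Shapiro–Wilk per group, then one-way ANOVA + Dunnett against the
control, or Kruskal–Wallis + Dunn (Holm-adjusted) when any group fails
normality. `two_group_test()` is the two-tailed unpaired Student's t.

Every analysis has a matching generator (`gen_calcium_trace()`,
`gen_vessel_network()`, `gen_permeability_stack()`,
`gen_extravasation_pair()`) that emits data plus a `ground_truth` record,
so the pipelines are tested end-to-end by parameter recovery.

## Worked example

```r
library(cardiochip)

# a healthy-condition recording: 1.04 Hz, 30 s at 10 ms
p  <- beat_train_params(mean_frequency = 1.04, ibi_cv = 0.05, seed = 7)
tr <- gen_calcium_trace(p)
analyze_calcium_trace(tr)
#> # A tibble: 1 × 9
#>   roi_id n_beats frequency cv_frequency mean_amplitude cv_amplitude
#>   <chr>    <int>     <dbl>        <dbl>          <dbl>        <dbl>
#> 1 roi1        31      1.02       0.0585          0.967       0.0548
#> # i 3 more variables: mean_time_to_peak <dbl>, mean_decay80 <dbl>,
#> #   duration <dbl>
```

The recovered frequency (1.02 Hz) matches the generator's 1.04 Hz to
within one-recording sampling error; the CV of frequency (0.058) reflects
the requested 5 % inter-beat-interval variability; the mean amplitude
(0.97 ΔF/F₀) sits slightly below the generated 1.0 because the percentile
baseline rides marginally above the true resting fluorescence (see the
methods vignette).

```r
# a microvascular field at the healthy condition: 22.9 um tubes, 64.5 %
net <- gen_vessel_network(vessel_network_params(seed = 1))
analyze_vessels(net$image, pixel_size = 1)
#> # A tibble: 1 × 7
#>   area_fraction total_length mean_diameter connectivity n_junctions ...
#> 1         0.647       32778.          20.7         4.59         225 ...

# permeability round trip at the diseased condition value
sim <- gen_permeability_stack(permeability_sim_params(9.2e-6))
analyze_permeability(sim$stack, sim$vessel_mask, sim$times,
                     diameter = 22.9, saturation_frac = Inf)$permeability
#> [1] 9.2e-06
```

`autoplot()` methods exist for traces and permeability fits;
`plot_beats()` and `plot_vessel_mask()` overlay detections on the data;
`tidy()`/`glance()` tidy comparison and permeability results.

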