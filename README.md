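# expalm

Dual-color single-molecule co-localization analysis for PALM and
Expansion-PALM (Ex-PALM) imaging of bacteria.

`expalm` measures nanometre-scale distances between two differently labeled
molecular species from two-color single-molecule localization microscopy
movies. It implements the complete analysis chain:

* **Spectral crosstalk** estimation from donor-only calibration frames and
  per-frame subtraction of bleed-through (`estimate_crosstalk()`,
  `correct_frames()`),
* **Single-molecule localization** by integrated-Gaussian fitting (compiled
  Levenberg–Marquardt core) in 2D or astigmatic-3D mode, with Thompson
  localization uncertainties (`detect_spots()`, `localize_stack()`,
  `calibrate_astigmatism()`),
* **Chromatic registration** with a non-rigid local-weighted-mean transform
  fitted on bead scans, in 2D or 3D (global axial shift plus 3D LWM), with
  fiducial registration error reporting (`fit_lwm()`, `compute_fre()`),
* **Merging of reappearing molecules** across blinking gaps
  (`merge_reappearances()`, `estimate_precision()`),
* **Co-localization analysis** with a local-density co-localization index and
  nearest-neighbor distance statistics, including group comparisons between
  experimental scenarios (`compute_ci()`, `classify_and_measure()`,
  `compare_groups()`).

A bundled synthetic two-channel movie generator (`simulate_movie()`)
emulates photoactivatable fluorescent proteins in rod-shaped bacteria —
EMCCD noise, blinking, chromatic aberration fields, crosstalk, optional
isotropic expansion — so the full pipeline can be exercised and validated
without raw acquisitions.

## Worked example

Simulate a small two-channel acquisition with calibration data, describe the
run in YAML, and execute the full pipeline:

```r
library(expalm)

# 1. Simulate a small dataset: a paired two-channel acquisition, bead
#    calibration scans, and donor-only crosstalk frames
dir <- tempfile("expalm-demo")
make_fixtures("positive",  seed = 5, dir = dir)
make_fixtures("beads",     seed = 5, dir = dir)
make_fixtures("crosstalk", seed = 5, dir = dir)

# 2. Describe the run in YAML (paths are relative to the YAML file)
yaml::write_yaml(list(
  mode   = "2D-PALM",
  movies = list(ch1 = "positive_ch1.tiff", ch2 = "positive_ch2.tiff"),
  donor  = list(ch1 = "donor_ch1.tiff", ch2 = "donor_ch2.tiff"),
  beads  = list(ch1 = "beads_ch1.tiff", ch2 = "beads_ch2.tiff"),
  localize = list(threshold = 5, min_photons = 500),
  merge    = list(radius = "palm"),
  coloc    = list(dB = 50),
  pixel_size = 82, seed = 5,
  out_dir = "run"), file.path(dir, "run.yaml"))

# 3. Run the full pipeline
cfg <- read_pipeline_config(file.path(dir, "run.yaml"))
out <- run_pipeline(cfg)
#> run complete: 253 + 226 molecules, 79.8% co-localizing, d = 33.85 nm

# 4. Inspect the per-acquisition summary
res <- jsonlite::read_json(file.path(out, "coloc_result.json"),
                           simplifyVector = TRUE)
str(res)
#> List of 8
#>  $ mean_ci  : num 0.873
#>  $ pct_coloc: num 79.8
#>  $ Nc       : int 202
#>  $ Nnc      : int 51
#>  $ dc       : num 24.2
#>  $ dnc      : num 72.2
#>  $ d        : num 33.9
#>  $ dB_nm    : int 50
```

Every stage writes its intermediate artifact into the run directory
(localization tables, the registration transform, the crosstalk map) and
appends a JSON log line to `pipeline.log`; re-running the same configuration
reproduces every output bit for bit.

The same run can be launched from a shell via the CLI entry point:

```sh
Rscript -e 'expalm::expalm_cli()' run --config run.yaml
```

## Replicated simulation studies

`run_colocalization_study()` simulates and analyzes many acquisitions of a
scenario — `"paired"` emitters at a truncated-normal distance (10 ± 5 nm
by default) as a positive control, or `"random"` independent placement as a
negative control — and collects per-acquisition summaries for group
comparisons with `compare_groups()`. `scripts/acceptance.R` runs the full
60-versus-60 study from the command line and writes a JSON summary.

## Documentation

The methods vignette (`vignettes/expalm-methods.Rmd`) documents the
quantitative methods (crosstalk factor, Thompson precision, LWM
registration and FRE, merging, the co-localization index), the pipeline
stage order and why it matters, the default parameter choices, and the
design and known realism limits of the synthetic generator.
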