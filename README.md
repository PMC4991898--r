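# gaitsemg

Bilateral lower-limb surface EMG (sEMG) asymmetry analysis in R.

Active rehabilitation devices are often controlled from *unilateral* sEMG
under a gait-symmetry assumption. `gaitsemg` implements a pipeline for
testing that assumption quantitatively: it compares the activity of the
left and right tibialis anterior (TA), soleus (SOL), lateral gastrocnemius
(LG) and medial gastrocnemius (MG) during quiet standing and steady
treadmill walking (1.0–4.5 km/h), and measures the irregularity of each
muscle's activation profile.

The pipeline:

1. **Preprocessing** — zero-phase 4th-order Butterworth band-pass
   (10–500 Hz) plus a Q = 30 notch at 50 Hz; sliding-window RMS envelope
   (125 ms, 50% overlap); normalization to percent of maximum voluntary
   contraction (%MVC), with the per-channel reference taken as the peak of
   a 1 s moving average of the MVC-trial envelope.
2. **Gait-cycle segmentation** — the cycle is defined by muscle activity
   rather than foot contact: it starts at the onset of right-TA
   contraction and runs until the right TA contracts again. Onsets are
   upward threshold crossings (baseline + 3 robust SD, sustained ≥ 50 ms,
   0.45 s refractory). Both limbs are cut on this one cycle clock.
3. **Phase normalization** — every cycle of every channel is resampled to
   100 points at equal phase intervals; cycles are pooled (across subjects
   if several) into ensemble curves (pointwise mean ± SD).
4. **Statistics** — per muscle and condition, a two-sided Wilcoxon
   rank-sum test of left vs right (exact by enumeration for small tie-free
   samples, tie-corrected normal approximation otherwise, α = 0.05), the
   absolute mean difference in %MVC points

   Δd = |mean_left − mean_right|,

   the left/right activity ratio, and the sample entropy of each side's
   ensemble curve,

   SampEn(m, r) = −log(A/B),

   where B and A are the numbers of template pairs within tolerance r
   (Chebyshev distance, in SD units) at lengths m and m + 1
   (defaults m = 2, r = 0.2).
5. **Synthetic data** — a seeded generator of multi-channel gait sEMG:
   band-limited (10–500 Hz) Gaussian carriers amplitude-modulated by
   per-muscle gait-phase activation templates (TA in swing plus a
   transition burst, SOL throughout stance, LG/MG late stance), amplitude
   growing with treadmill speed, configurable per-channel left/right gains
   and ripple. Ground-truth onset times and activation levels ride along,
   so every pipeline stage is verifiable without laboratory recordings.

## Worked example

Simulate one subject walking 15 s at 3 km/h with a 1.3× stronger left
soleus, then run the full dynamic analysis:

```r
library(gaitsemg)
library(dplyr)

params <- synth_params(duration = 15, speed = 3, seed = 42,
                       asymmetry = c(left_SOL = 1.3))
walk    <- synth_gait_emg(params)
mvc_ref <- synth_mvc_reference(params)

report <- analyze_dynamic(list(walk), mvc_ref)
report |>
  select(muscle, speed, n_cycles, mean_left, mean_right,
         delta_d, ratio, p_value)
#> # A tibble: 4 × 8
#>   muscle speed n_cycles mean_left mean_right delta_d ratio  p_value
#>   <chr>  <dbl>    <int>     <dbl>      <dbl>   <dbl> <dbl>    <dbl>
#> 1 TA         3       18      47.2       46.0   1.28  1.03  0.207
#> 2 SOL        3       18      77.7       59.1  18.6   1.32  0.000616
#> 3 LG         3       18      48.3       48.9   0.620 0.987 0.570
#> 4 MG         3       18      49.2       48.3   0.878 1.02  0.140
```

Reading the output: means are in %MVC averaged over the 100-point
ensemble curve; the injected soleus asymmetry comes back as a left/right
ratio of 1.32 with Δd ≈ 18.6 %MVC points and a clearly significant
rank-sum p, while the symmetric muscles sit near ratio 1 with
non-significant p. `report_ensembles(report)` returns the underlying
curves, `autoplot(report)` and `autoplot(report_ensembles(report))` plot
them, and `write_report(report, "out/")` writes the p-value grid,
sample-entropy grid, per-speed means and a JSON manifest.

For standing data use `synth_static_emg()` + `analyze_static()`; for your
own recordings, read delimited text with `read_recording()` and a
`channel_map()`, and build the MVC reference with `rms_envelope()` +
`extract_mvc()` on your MVC trials.

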