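# qcmr

Simulation and motion-compensated reconstruction toolkit for free-breathing
3D joint T1/T1rho/T2 cardiac mapping with two-point Dixon water/fat
encoding.

Myocardial T1, T1rho, and T2 relaxation times are contrast-agent-free
markers of fibrosis, edema, and fatty infiltration. `qcmr` implements, end
to end and at desk scale, a quantitative-MRI method that encodes all three
parameters in one free-breathing scan: a 5-heartbeat magnetization
preparation schedule (inversion recovery with TI = 250 ms; none; spin-lock,
TSL = 40 ms at 400 Hz; T2 preparation, 40 ms; none) with a segmented
spoiled gradient-echo readout (16 x TR 6.71 ms = 107 ms acquisition window,
TE1/TE2 = 2.38/4.76 ms), variable-density Cartesian sampling with spiral
profile order and golden-angle increments within and across contrasts,
image-navigator motion estimation with respiratory binning, a non-rigid
motion-compensated encoding operator

```
E(c) = sum_b  A_b(c) . F . S . U_b
```

(per-bin sampling masks `A_b`, Fourier transform `F`, coil sensitivities
`S`, bin deformations `U_b`), patch-based higher-order low-rank
reconstruction by ADMM

```
|| E X - K ||_F^2 + lambda sum_v ||T_v||_*  (lambda = 0.04, mu = 0.1)
```

with HOSVD truncation of similar-patch tensors (5x5x5 patches, 20 similar
patches, 20^3 search window), exact two-point Dixon water/fat separation
with smooth background-phase correction, and voxelwise estimation of
(T1, T1rho, T2) by maximum-inner-product matching against a Bloch-simulated
dictionary (grids T1 = [50:50:600, 600:15:1800, 1800:50:2200,
2200:100:3000] ms, T1rho = T2 = [5:5:20, 20:1.5:80, 80:4:100, 100:10:300,
300:100:600] ms, constrained to T2 <= T1rho <= T1).

Everything runs on synthetic digital phantoms generated by the package
itself -- no scanner data is required -- so every stage can be validated
against known ground truth. The intended audience is researchers studying
quantitative cardiac MRI reconstruction who want a compact, fully
inspectable reference implementation of the whole chain.

## Worked example

Simulate the study conditions -- a 9-vial phantom spanning the myocardial
parameter range in a 64 x 64 x 16 volume (2 mm isotropic), 6 coils, 6-fold
per-contrast undersampling, 4 respiratory bins of 8 mm sinusoidal
breathing, 70 dB object SNR -- reconstruct with the full HD-PROST chain,
and match against the full dictionary:

```r
library(qcmr)
res <- run_pipeline(qcmr_config(list(seed = 1)))
res$stats[3:4, c("label", "t1_true", "t1_mean", "t1rho_true", "t1rho_mean",
                 "t2_true", "t2_mean")]
```

```
  label t1_true  t1_mean t1rho_true t1rho_mean t2_true  t2_mean
3     3     900  905.344         50     51.832      35   35.034
4     4    1095 1095.014         56     55.952      44   44.363
```

Vial 4 carries the myocardium-like triplet T1/T1rho/T2 = 1095/56/44 ms;
its mean estimates over ~1000 voxels land within 0.1/0.1/0.4 ms of the
truth despite 6-fold undersampling, breathing motion, and noise, because
the motion-compensated reconstruction plus dictionary quantization snap
most voxels onto the correct grid entry. `res$maps` holds the
voxelwise maps (`NA` outside the signal mask), `res$stats` per-vial means,
SDs and median absolute percentage errors against the ground truth, and
`res$recon$residual_history` the data-consistency residual of the ADMM.
With `output_dir` set, the maps are written as NIfTI, the k-space bundle
and reconstruction as RDS, the per-vial statistics as CSV, and a JSON
manifest (seed, configuration hash, timings) that makes the run exactly
reproducible.

Individual stages are exported and can be used on their own:
`build_dictionary()`, `make_vial_phantom()`, `generate_caspr_pattern()`,
`simulate_acquisition()`, `estimate_translation_ncc()`, `assign_bins()`,
`correct_translation_kspace()`, `register_ffd()`,
`compose_encoding_operator()`, `hd_prost_reconstruct()`,
`dixon_separate()`, `match_dictionary()`, `fit_ir_se()`, `fit_monoexp()`.
A thin command-line driver with `simulate` / `recon` / `map` / `all`
subcommands is installed as `exec/qcmr`.

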