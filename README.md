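# swtreg

Rigid 2D registration of planning CT and setup cone-beam CT (CBCT) slices
for image-guided radiotherapy, combining intensity and *gradient-image*
normalized mutual information.

Intensity-based mutual-information registration scores a candidate
alignment purely from the joint gray-value histogram and ignores where
gray values sit in the image. `swtreg` restores that spatial information
by synthesizing an edge-dominant **gradient image** of each input with the
stationary (undecimated, à-trous) wavelet transform — decompose to depth
3, zero the low-frequency approximation bands of every level, inverse
transform the remaining LH/HL/HH detail bands — and fusing the normalized
mutual information of the intensity images (NMI_i) with that of the
gradient images (NMI_g):

    NMI  = f(v) NMI_i + (1 - f(v)) NMI_g
    f(v) = 1 / (1 + exp(-(v - 0.5)/T)),  T = 0.04
    v    = ((NMI_i - 1) + (NMI_g - 1)) / 2

where `NMI(A,B) = (H(A) + H(B)) / H(A,B)` in [1, 2]. The correction
(dx, dy, theta) is found by Powell's direction-set method with Brent line
searches; the intensity NMI is optimized first and the fused measure
refines from its optimum. An intensity-only baseline (`mode = "mi_only"`)
is built in for comparisons.

The package also provides image I/O (single-frame DICOM, PNG, TIFF, CSV),
CBCT-to-CT grid resampling, a seeded anatomical phantom generator with
CBCT-like degradation, and the two standard validation harnesses
(preset-transform recovery; shift linearity under manual pre-shifts).

## Worked example

```r
library(swtreg)

ref <- makePhantom(phantomSpec(seed = 1))           # 256 x 256 CT-like slice
flt <- applyRigid(ref, rigidTransform(10, 15, -3))  # misalign: 10 px, 15 px, -3 deg
res <- registerImages(ref, flt)
res
#> RegistrationResult (proposed mode)
#>   recovered: dx=-9.199 dy=-15.502 px, theta=2.997 deg
#>   combined measure 1.88304 (NMI_i 1.88368, NMI_g 1.60277)
#>   MSE 5.1119 after 470 evaluations, 1 sweep(s)

round(transformParams(invertTransform(res@transform)), 3)
#>     dx     dy  theta
#>  9.997 15.000 -2.997
mseError(ref, flt)
#> [1] 154.32
```

The recovered correction maps the floating image back onto the reference;
its inverse, `(9.997, 15.000, -2.997)`, is the estimate of the applied
misalignment — accurate to a few thousandths of a pixel/degree here. The
root-mean-square gray difference drops from 154.3 (misaligned) to 5.1
(the residual bilinear smoothing at region boundaries).

A command-line front end over the same functions lives in
`inst/scripts/swtreg.R` (`register`, `gradient`, `measure`, `phantom`
subcommands).

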