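Package: stackfuse
Title: Content-Aware Multi-Focus Fusion of Brightfield Microscopy Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs extended-depth-of-field (EDoF) images from axially
    undersampled brightfield z-stacks. Provides multi-page TIFF stack I/O with
    white balancing and axial decimation, a classical wavelet multi-scale
    decomposition fusion baseline used to build EDoF targets from fully
    sampled stacks, a content-aware encoder/decoder residual network that
    fuses any number of focal planes by element-wise maximum over shared
    per-plane features and is trained with a combined MAE + SSIM + FFT loss,
    image-similarity metrics (SSIM, Pearson correlation, HaarPSI), and a
    synthetic blood-film z-stack simulator with depth-dependent defocus so
    the whole pipeline is testable without microscope data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
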