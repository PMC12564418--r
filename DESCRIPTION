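Package: ftirauth
Title: Chemometric Authentication of Meat Origin from ATR-FTIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete chemometric workflow for authenticating the
    geographical origin of meat from mid-infrared attenuated total
    reflectance (ATR-FTIR) absorbance spectra. Provides labeled spectral
    data containers with replicate averaging and region masking, eleven
    spectral pre-processing operators (Savitzky-Golay derivatives,
    SNV, MSC, detrending, median filtering, quantile normalization,
    orthogonal signal correction, ATR penetration-depth correction),
    PCA with Hotelling T-squared and Q-residual outlier rejection,
    SIMCA class modeling with Coomans coordinates, PCA-LDA and PLS-LDA
    discriminant classifiers, PLS1 regression with VIP scores, RBF-kernel
    support vector regression with permutation importance, a feed-forward
    neural-network classifier with region-of-importance mapping, three
    validation schemes (training, leave-one-out, Venetian blinds), a
    two-class synthetic FTIR spectrum generator, and a factorial
    experiment driver producing tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
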