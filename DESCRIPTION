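Package: canopycomplexity
Title: Box Dimension and Canopy Entropy Indices of Forest Structural Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes two holistic structural-complexity indices for
    height-normalized forest point clouds: the box dimension (Db), a
    fractal box-counting estimate obtained by recursive voxel halving and
    log-log regression, and canopy entropy (CE), the Pythagorean
    combination of three plane-wise differential entropies of a kernel
    density estimate, preceded by a Mann-Kendall-based detection and
    voxel-centre correction of vertical sampling-density bias. Includes
    the statistical machinery to compare the indices (Pearson
    correlation, Deming errors-in-variables regression with jackknife
    confidence intervals, per-site fits, zero-intercept power-law
    runtime scaling fits), synthetic point-cloud generators with known
    fractal dimension (planes, lines, uniform cubes, Menger sponges,
    density-biased canopies), and a batch pipeline over directories of
    LAS or XYZ clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
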