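#!/usr/bin/env Rscript
# Re-estimates the default PF-10 norm-based scoring coefficients from the 21
# published (raw, norm-based) score pairs and prints the constants stored in
# default_norm_coefficients(). Run from the repository root:
#   Rscript scripts/regenerate-norm-coefficients.R
suppressPackageStartupMessages(library(pfhaqlink))

coef <- fit_norm_coefficients(pf10_norm_pairs())
cat(sprintf("mu    = %.10f\nsigma = %.10f\n", coef$mu, coef$sigma))

pairs <- pf10_norm_pairs()
pred <- pf10_norm_based(pairs$raw, coef = coef)
ok <- all(sprintf("%.1f", pred) == sprintf("%.1f", pairs$norm))
cat("reproduces all 21 published norm-based values to one decimal:", ok, "\n")
stopifnot(ok)
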