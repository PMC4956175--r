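#!/usr/bin/env Rscript
# Build the two synthetic species used throughout the analysis: a mouse-like
# cortex (33 areas, <d> = 4.54 mm, lambda = 0.78 mm^-1, density 0.68) and a
# macaque-like cortex (<d> = 26.35 mm, lambda = 0.188 mm^-1, density 0.66).
# Both are jittered-grid sheets whose distance distributions are unimodal with
# d_max/<d> near 2.2, so the two brains land on a common adimensional
# template with gamma = lambda * <d> of about 3.5 and 5.

library(edrconnectome)

out <- "results/species"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mouse <- mouse_like_species(seed = 1001)
macaque <- macaque_like_species(seed = 2001)

for (sp in list(mouse, macaque)) {
  write_species(sp, file.path(out, sp$name))
  st <- distance_stats(sp$D)
  cat(sprintf("%s: <d> = %.3f mm, d_max = %.2f mm (ratio %.2f), gamma = %.2f, density %.3f\n",
              sp$name, st$mean, st$max, st$ratio, sp$gamma,
              graph_density(sp$connectome)))
}
cat("fixtures written under", out, "\n")
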