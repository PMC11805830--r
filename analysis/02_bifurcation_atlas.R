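#!/usr/bin/env Rscript
# Bifurcation atlas in the (m5, m2) plane for the standard frame
# (m1, m3, m4) = (40, 2.5, 7.142857...).
#
# What this finds: the plane splits into a tumor-free-stable region at
# high m5 (transcritical line m5 = m4), controlled-coexistence regions
# (stable node / stable focus) at moderate immunosuppression, an
# oscillatory window beyond the Hopf curve that is still controllable
# (R4A) until the homoclinic bifurcation destroys the limit cycle (R4B),
# and escape-only regions inside the fold wedge.  The fold and Hopf curves
# meet at the Bogdanov-Takens point, the origin of the homoclinic curve.
# The homoclinic m2 at m5 = 1 is located by fate bisection.

library(cartnode)

out_dir <- "results/02_atlas"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
frame <- preset("fig1b_frame")

atlas <- region_atlas(frame$m1, frame$m3, frame$m4,
                      m2_range = c(1, 45), m5_range = c(0.25, 10),
                      resolution = 41, resolve_r4 = FALSE)
write_atlas(atlas, out_dir)
cat("region counts over the 41x41 raster:\n")
print(table(atlas$raster$region))

bt <- bt_point(frame$m1, frame$m3, frame$m4)
cat(sprintf("\nBogdanov-Takens point: (m5, m2) = (%.6f, %.4f)\n",
            bt$m5, bt$m2))

hom <- locate_homoclinic(frame$m1, frame$m3, frame$m4, m5 = 1,
                         m2_bracket = c(25, 33), rtol = 2e-3)
cat(sprintf("homoclinic crossing at m5 = 1: m2 = %.3f (%s below, %s above)\n",
            hom$m2_hom, hom$fate_lower, hom$fate_upper))
jsonlite::write_json(list(bt = bt, homoclinic_m5_1 = hom),
                     file.path(out_dir, "codim2_and_homoclinic.json"),
                     auto_unbox = TRUE, digits = NA)
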