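#!/usr/bin/env Rscript
# Stage 3: mechanics chain on the measured dimer table.
#
# Angle scatter -> equipartition torsional stiffness of the hinge ->
# apparent cantilever stiffness; angle-vs-separation regressions and
# 100-point running averages -> inter-head tension per nm -> tensions at
# the lattice separations -> ring-separation estimates -> stiffness of the
# elastic inter-head linkage.

suppressPackageStartupMessages(library(dyneinflex))

dimers <- utils::read.delim("results/dimers.tsv")
superposed <- utils::read.delim("results/superposed.tsv")
geom <- motor_geometry()

rep <- mechanics_report(dimers, superposed$theta_deg, geom,
                        mode = "geometric", window = 100L)

cat(sprintf("n = %d offset dimers, %d superposed dimers\n",
            rep$n, rep$superposed$n))
cat(sprintf("angles (mean +/- sd): leading %.1f +/- %.1f, trailing %.1f +/- %.1f, superposed %.1f +/- %.1f deg\n",
            rep$leading$phi_mean, rep$leading$sigma_deg,
            rep$trailing$phi_mean, rep$trailing$sigma_deg,
            rep$superposed$phi_mean, rep$superposed$sigma_deg))
cat(sprintf("torsional stiffness: leading %.0f, trailing %.0f, superposed %.0f pN nm rad^-2\n",
            rep$leading$kappa, rep$trailing$kappa, rep$superposed$kappa))
cat(sprintf("cantilever stiffness: leading %.2f, trailing %.2f, superposed %.2f pN/nm\n",
            rep$leading$cantilever_k, rep$trailing$cantilever_k,
            rep$superposed$cantilever_k))
cat(sprintf("regressions: trailing slope %+.3f, leading slope %+.3f deg/nm (pairwise %+.2f)\n",
            rep$fit_trailing$slope, rep$fit_leading$slope, rep$pairwise_slope))
cat(sprintf("tension per nm of separation: %.3f (lead) / %.3f (trail), mean %.3f pN\n",
            rep$tension_per_nm_leading, rep$tension_per_nm_trailing,
            rep$tension_per_nm_mean))
cat("tension at separations (pN):",
    paste(sprintf("%s nm: %.2f", names(rep$tensions_at), rep$tensions_at),
          collapse = ", "), "\n")
cat(sprintf("tether stiffness estimate: %.4f pN/nm\n", rep$tether_stiffness))

# the abundance ratio of superposed vs offset rings at superposed
# stalkheads gives the head-head association equilibrium constant; with
# generated counts this mirrors the generator's class weights
near_zero <- sum(dimers$stalkhead_separation_nm < 4)
if (near_zero > 0)
  cat(sprintf("equilibrium constant (superposed/offset at <4 nm): %.1f\n",
              equilibrium_constant(rep$superposed$n, near_zero)))

writeLines(jsonlite::toJSON(report_numbers(rep),
                            auto_unbox = TRUE, digits = NA, pretty = TRUE),
           "results/mechanics.json")
cat("wrote results/mechanics.json\n")
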