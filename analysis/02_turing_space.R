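#!/usr/bin/env Rscript

# Turing space of the coexistence states.
#
# Maps, over the treatment plane, where an ODE-stable coexistence
# equilibrium is destabilised by diffusion (dispersion-relation test at the
# critical wavenumber). The instability bands hug the boundary of the
# stable-coexistence region; the effector-cell diffusivity delta_u sets
# their width while the IL-2 diffusivity delta_w has no visible effect.
# Also exports a dispersion curve for the reference Turing-unstable point.

suppressPackageStartupMessages(library(turimm))
dir.create("results", showWarnings = FALSE)

su <- seq(0, 0.03, length.out = 151)
sw <- seq(0, 6, length.out = 121)

for (a in c(0.02, 0.07, 0.1)) {
  message(sprintf("Turing scan at alpha = %.2f, delta = 100 ...", a))
  scan <- scan_turing_plane(reference_nondim(alpha = a), su, sw)
  write_scan_csv(scan, sprintf("results/turing_plane_alpha%.2f.csv", a))
  png(sprintf("results/turing_plane_alpha%.2f.png", a), 700, 600)
  labs <- c("no_coexistence", "coex_stable_all", "coex_turing_unstable")
  image(su, sw, matrix(match(scan, labs), length(su)),
        col = c("grey85", "forestgreen", "firebrick"),
        xlab = "sigma_u", ylab = "sigma_w",
        main = sprintf("Turing space, alpha = %.2f", a))
  legend("topright", fill = c("grey85", "forestgreen", "firebrick"),
         legend = labs, bg = "white")
  dev.off()
  message(sprintf("  Turing-unstable cells: %d",
                  sum(scan == "coex_turing_unstable")))
}

# delta_w insensitivity: identical Turing-cell counts at delta_w = 100, 1000
c100 <- sum(scan_turing_plane(reference_nondim(alpha = 0.07), su, sw) ==
              "coex_turing_unstable")
c1000 <- sum(scan_turing_plane(reference_nondim(alpha = 0.07,
                                             delta_w = 1000), su, sw) ==
               "coex_turing_unstable")
message(sprintf("delta_w sweep: %d Turing cells at delta_w=100, %d at 1000",
                c100, c1000))

# dispersion curve at a Turing-unstable reference point
p <- reference_nondim(sigma_u = 0.018, sigma_w = 0.5)
eq <- Filter(function(e) e$stable, coexistence_equilibria(p))[[1]]
J <- reaction_jacobian(eq$state, p)
dcurve <- dispersion_curve(J, p$delta_u, p$delta_w,
                           k2 = seq(0, 0.15, length.out = 601))
write.csv(dcurve, "results/dispersion_curve.csv", row.names = FALSE)
tt <- turing_test(p, eq)
message(sprintf("reference point: k_c^2 = %.4f, max growth rate = %.4f",
                tt$k_c2, max(dcurve$max_re)))
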