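#!/usr/bin/env Rscript

# Steady state and stability of the six-node AR/PI3K/PTEN/p65/IkB/c-Myc
# network. Writes the fixed point and the spectrum of the system matrix to
# results/, and cross-checks the linear solve against long-run noise-free
# integration.

suppressPackageStartupMessages(library(andronet))
dir.create("results", showWarnings = FALSE)

model <- ar_nfkb_model()
fp <- fixed_point(model)

cat("Fixed point of the unperturbed network (activity, arbitrary units):\n")
print(round(fp$x_star, 6))
cat(sprintf("\nstable: %s (max Re(eig) = %.4f); feasible: %s (min x* = %.6f)\n",
            fp$stable, max(Re(fp$eigenvalues)), fp$feasible, min(fp$x_star)))

traj <- simulate_network(model, x0 = c(1, 1.2, 1.4, 1.6, 1.8, 2),
                         t_end = 500, dt = 0.001, output_stride = 5000)
final <- traj$states[nrow(traj$states), ]
cat(sprintf("long-run Euler (t = 500) agrees with the solve to %.2e\n",
            max(abs(final - fp$x_star))))

write.csv(data.frame(node = model$labels, x_star = unname(fp$x_star),
                     euler_t500 = unname(final)),
          "results/fixed_point.csv", row.names = FALSE)
write.csv(data.frame(re = Re(fp$eigenvalues), im = Im(fp$eigenvalues)),
          "results/eigenvalues.csv", row.names = FALSE)
cat("wrote results/fixed_point.csv, results/eigenvalues.csv\n")
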