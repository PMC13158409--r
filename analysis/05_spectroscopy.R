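#!/usr/bin/env Rscript
# Headgroup order and local polarity: a Laurdan generalized-polarization
# dose series and spin-label EPR parameter extraction (mobility ratio at
# room temperature, hyperfine coupling at 77 K).

suppressPackageStartupMessages(library(slbtools))
dir.create("results", showWarnings = FALSE)

# Laurdan: drug dose suppresses the relaxed 490 nm band -> GP rises
ratios <- c(0, 1/100, 1/50, 1/25, 1/10, 1/5)
doses <- data.frame(ratio = ratios,
                    a490_over_a440 = seq(1.25, 0.75, length.out = 6))
spectra <- gen_laurdan_spectra(doses, replicates = 3, noise_sd = 0.005,
                               seed = 1)
gp <- gp_dose_series(spectra)
cat("Laurdan GP dose series (mean +/- sd over triplicates):\n")
print(gp, digits = 3, row.names = FALSE)
write.csv(gp, "results/laurdan_gp.csv", row.names = FALSE)
cat(sprintf("GP increases monotonically with dose: %.3f -> %.3f\n\n",
            gp$gp_mean[1], gp$gp_mean[nrow(gp)]))

# room-temperature EPR: mobility ratio h0/h- with and without drug
room <- list(
  control = gen_epr_spectrum(c(330.5, 332, 333.5), widths = 0.25,
                             amplitudes = c(1, 1, 0.85), noise_sd = 0.01,
                             seed = 2),
  cpz = gen_epr_spectrum(c(330.5, 332, 333.5), widths = 0.25,
                         amplitudes = c(1, 1, 0.75), noise_sd = 0.01,
                         seed = 3)
)
h_tab <- data.frame(
  condition = names(room),
  h0_over_hminus = vapply(room, epr_line_ratio, numeric(1)))
cat("Room-temperature mobility ratios (higher = stiffer environment):\n")
print(h_tab, digits = 4, row.names = FALSE)

# cryo EPR: hyperfine coupling 2Az as a polarity proxy
cryo <- list(
  control = gen_epr_spectrum(c(330, 333.5, 337), widths = 0.4,
                             amplitudes = c(0.6, 1, 0.6), noise_sd = 0.01,
                             seed = 4, shape = "cryo"),
  cpz = gen_epr_spectrum(c(330.15, 333.5, 336.85), widths = 0.4,
                         amplitudes = c(0.6, 1, 0.6), noise_sd = 0.01,
                         seed = 5, shape = "cryo")
)
az <- lapply(cryo, epr_hyperfine_2Az)
a_tab <- data.frame(
  condition = names(cryo),
  a_z_mT = vapply(az, `[[`, numeric(1), "a_z"),
  se_mT = vapply(az, `[[`, numeric(1), "se"))
cat("\nCryo hyperfine couplings (lower 2Az = drier bilayer core):\n")
print(a_tab, digits = 4, row.names = FALSE)
write.csv(merge(h_tab, a_tab, all = TRUE), "results/epr_parameters.csv",
          row.names = FALSE)

cat(sprintf("\nThe drug condition lowers 2Az by %.2f mT, the direction of a\n",
            2 * (a_tab$a_z_mT[1] - a_tab$a_z_mT[2])))
cat("reduced-polarity (dehydrated) membrane core.\n")
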