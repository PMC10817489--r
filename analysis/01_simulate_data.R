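#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Raw plate diameters and time-course concentrations are not available for
# these assay designs, so the analysis runs on synthetic datasets generated
# with the statistical structure the assays describe: 5-concentration plate designs
# with 6 colonies per plate, and triplicate batch Cr(VI) depletion curves
# at the three fitted parameter sets, sampled on the 0-30 day schedule with
# 5% relative measurement noise.

suppressPackageStartupMessages(library(mycosorb))

seed <- 20240105L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# -- plate tolerance tables ---------------------------------------------------
# Hill parameters chosen to span the observed tolerance spectrum: a strongly
# As(V)-tolerant strain (IC50 near the top of the design), a mid-range one,
# and a Cr(VI)-sensitive one (IC50 near the bottom of its design).
plate_specs <- list(
  list(strain = "strain_A", metal = "AsV", ic50 = 10.0, h = 2.0),
  list(strain = "strain_B", metal = "AsV", ic50 = 6.0, h = 1.5),
  list(strain = "strain_C", metal = "CrVI", ic50 = 0.25, h = 1.2)
)
plates <- do.call(rbind, lapply(seq_along(plate_specs), function(i) {
  s <- plate_specs[[i]]
  d <- simulate_tolerance(s$ic50, s$h,
                          concentrations = default_plate_concentrations(s$metal),
                          seed = seed + i, strain = s$strain, metal = s$metal)
  plate_rows(d)
}))
write_plate_table(plates, file.path(out_dir, "plate_table.csv"),
                  overwrite = TRUE)
cat(sprintf("wrote %s: %d rows, %d strains\n",
            file.path(out_dir, "plate_table.csv"), nrow(plates),
            length(unique(plates$strain))))

# -- batch sorption time courses ----------------------------------------------
kin <- read.csv(system.file("extdata", "kinetic_parameters.csv",
                            package = "mycosorb"))
for (i in seq_len(nrow(kin))) {
  r <- kin[i, ]
  m <- kinetic_model(r$order, r$k, langmuir(r$q_max, r$K_L))
  sim <- simulate_timecourse(m, C0 = r$C0_mg_per_L, V = r$V_L, Ma = r$Ma_g,
                             seed = seed + 100L + i,
                             label = r$label, metal = r$metal)
  path <- file.path(out_dir, paste0(r$label, "_timecourse.csv"))
  write_batch_sorption(sim, path, overwrite = TRUE)
  cat(sprintf("wrote %s (%d measurements, %d censored)\n", path,
              nrow(sim$data), sum(sim$data$censored)))
}

write_provenance(file.path(out_dir, "provenance.json"),
                 inputs = list(kinetic_parameters = "inst/extdata/kinetic_parameters.csv"),
                 seed = seed,
                 tolerances = list(rel_noise_sd = 0.05, diameter_cv = 0.05))
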