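#!/usr/bin/env Rscript
# Build the synthetic bilayer datasets every later analysis step consumes:
#   - three randomly mixed 6000-lipid bilayers (the t = 0 state of a
#     phase-separation run),
#   - a striped phase-separated frame with planted Lo/Ld thicknesses,
#   - a circular-domain frame,
#   - two coarsening series with different growth exponents (0.5 vs 0.3),
#     emulating an unperturbed and a retarded (protein-like) condition.
# Frames are written as GRO files with JSON ground-truth sidecars under
# scratch/data/; a small manifest goes to results/.

suppressPackageStartupMessages({
  library(bilayerphase)
  library(jsonlite)
})

data_dir <- "scratch/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

comp <- composition_spec(3000)  # 1502 DPPC : 900 DUPC : 598 CHOL per leaflet
manifest <- list()
save_truth <- function(truth, name) {
  truth$lipids <- NULL  # per-lipid labels live in the frame order; keep sidecars small
  write_json(truth, file.path(data_dir, paste0(name, ".truth.json")),
             auto_unbox = TRUE, digits = NA, force = TRUE)
}

for (s in 1:3) {
  name <- sprintf("mixed_seed%d", s)
  sim <- random_mixed_frame(comp, box = c(400, 400), seed = s)
  write_gro_frames(sim$frame, file.path(data_dir, paste0(name, ".gro")))
  save_truth(sim$truth, name)
  manifest[[length(manifest) + 1]] <- data.frame(
    dataset = name, kind = "mixed", frames = 1, seed = s)
}

stripe <- striped_frame(comp, box = c(400, 400), stripe_width = 120, seed = 101)
write_gro_frames(stripe$frame, file.path(data_dir, "stripe.gro"))
save_truth(stripe$truth, "stripe")
manifest[[length(manifest) + 1]] <- data.frame(
  dataset = "stripe", kind = "stripe", frames = 1, seed = 101)

wide <- striped_frame(comp, box = c(400, 400), stripe_width = 200, seed = 102)
prot <- place_proteins(wide$frame, wide$truth,
                       placement = c(Lo = 3, Ld = 1, interface = 6), seed = 103)
write_gro_frames(prot$frame, file.path(data_dir, "stripe_proteins.gro"))
save_truth(prot$truth, "stripe_proteins")
manifest[[length(manifest) + 1]] <- data.frame(
  dataset = "stripe_proteins", kind = "stripe+proteins", frames = 1, seed = 102)

circ <- circular_domain_frame(comp, box = c(400, 400), radii = c(30, 50), seed = 104)
write_gro_frames(circ$frame, file.path(data_dir, "circles.gro"))
save_truth(circ$truth, "circles")
manifest[[length(manifest) + 1]] <- data.frame(
  dataset = "circles", kind = "circles", frames = 1, seed = 104)

# two coarsening conditions anchored to the same initial radius; the slow
# exponent mimics the retarding effect of an interface-active protein
fast <- coarsening_series(comp, box = c(400, 400), alpha = 0.5, n_frames = 10,
                          t_end = 5, seed = 105, r_end = 50)
slow <- coarsening_series(comp, box = c(400, 400), alpha = 0.3, n_frames = 10,
                          t_end = 5, seed = 106,
                          r_end = 50 * (0.5 / 5)^(0.5 - 0.3))
for (nm in c("fast", "slow")) {
  co <- get(nm)
  write_gro_frames(co$frames, file.path(data_dir, paste0("coarsen_", nm, ".gro")))
  write_json(co$truth_series, file.path(data_dir, paste0("coarsen_", nm, ".truth.json")),
             digits = NA)
  manifest[[length(manifest) + 1]] <- data.frame(
    dataset = paste0("coarsen_", nm), kind = "coarsening",
    frames = length(co$frames), seed = if (nm == "fast") 105 else 106)
}

manifest <- do.call(rbind, manifest)
write.csv(manifest, "results/datasets.csv", row.names = FALSE)
message("wrote ", nrow(manifest), " datasets to ", data_dir)
print(manifest)
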