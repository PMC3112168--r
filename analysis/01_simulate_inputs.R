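#!/usr/bin/env Rscript
# Generates every synthetic input the downstream analyses consume:
# a punctate surface-labelling image with ground truth, tidy I-V families,
# current traces, designed C-terminal sequences, and gradient profiles.
# Outputs land under results/inputs/.

suppressMessages(library(raftpuncta))
seed <- 20110610L
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Punctate image: many small, bright, well-separated puncta over a dim
## background -- the appearance of surface-labelled alpha2delta clusters.
field <- generate_particle_field(200, mean_area = 20, dispersion = 0.4,
                                 frame = c(768L, 768L), min_separation = 16,
                                 peak_intensity = 800, seed = seed)
img <- render_image(field, psf_sigma = 1, background = 100,
                    noise = "poisson_gaussian", read_noise_sd = 5,
                    seed = seed + 1L)
write_image_tiff(img, file.path(out, "puncta_synthetic.tif"))
cat(sprintf("image: %d puncta, C_t = %.0f px^2 -> %s\n",
            field$n_t, field$c_t, file.path(out, "puncta_synthetic.tif")))

## I-V families for the two-group contrast (with vs without the auxiliary
## subunit): 4-fold Imax enhancement, -13 mV V50 hyperpolarisation.
pr <- preset_alpha2delta_groups()
ds <- generate_iv_dataset(pr, n_cells = 10, noise_sd = 0.5, seed = seed + 2L)
write_iv_csv(ds, file.path(out, "iv_families.csv"))
cat(sprintf("i-v: %d cells x %d voltages -> %s\n",
            length(unique(ds$cell_id)), length(unique(ds$voltage_mV)),
            file.path(out, "iv_families.csv")))

## Current traces for kinetic fitting.
traces <- lapply(1:8, function(i) {
  generate_current_trace(tau_act = 2, tau_inact = 50, amplitude = -60,
                         noise_sd = 3, seed = seed + 10L + i)
})
trace_df <- do.call(rbind, lapply(seq_along(traces), function(i) {
  data.frame(trace_id = i, time_ms = traces[[i]]$time_ms,
             current = traces[[i]]$current)
}))
utils::write.csv(trace_df, file.path(out, "current_traces.csv"),
                 row.names = FALSE)
cat(sprintf("traces: %d sweeps -> %s\n", length(traces),
            file.path(out, "current_traces.csv")))

## Designed C-termini: intact motif, TM+tail-disrupted, and no-motif control.
panel <- list(
  generate_sequences("intact_gpi", id = "intact_motif", seed = seed + 21L),
  generate_sequences("disrupted_tail", id = "tm_tail_swap", seed = seed + 22L),
  generate_sequences("no_motif", id = "polyK_control", seed = seed + 23L))
write_fasta_records(panel, file.path(out, "designed_ctermini.fasta"))
cat(sprintf("sequences: %d records -> %s\n", length(panel),
            file.path(out, "designed_ctermini.fasta")))

## Gradient profiles: a raft-resident protein (~20% raft signal), the same
## protein after enzyme treatment (raft signal lost), and a raft-only marker.
profiles <- list(
  partial_raft = generate_gradient_profile(0.2, noise_sd = 1, seed = seed + 31L),
  post_enzyme = generate_gradient_profile(0.02, noise_sd = 1, seed = seed + 32L),
  raft_marker = generate_gradient_profile(0.9, noise_sd = 1, seed = seed + 33L))
for (nm in names(profiles)) {
  write_gradient_csv(profiles[[nm]], file.path(out, paste0("gradient_", nm, ".csv")))
}
cat(sprintf("gradients: %d profiles -> %s/gradient_*.csv\n",
            length(profiles), out))
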