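#!/usr/bin/env Rscript
# Step 1 — digital phantom generation.
#
# Builds two digital breast-tumor phantoms with known ground truth:
#   (a) a shimmed scene (no B0 inhomogeneity) used for exact round-trip
#       validation of the quantification chain, and
#   (b) a scene with a smooth in-plane B0 field (up to 0.3 ppm) and mild
#       noise, used to quantify the benefit of Z-spectrum correction.
# Writes every acquired volume as NIfTI plus the ground-truth maps and two
# simulated reader masks.

library(aptnac)

out_dir <- "results/01_phantom"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

scenes <- list(
  shimmed = phantom_scene(dim = c(24, 24, 8), core_radius = 2.5, seed = 101),
  b0field = phantom_scene(dim = c(24, 24, 8), core_radius = 2.5, seed = 102,
                          noise_sd = 0.005,
                          b0_coef = c(0.05, 0.15, -0.10, 0.02, 0.05, -0.03)))

for (nm in names(scenes)) {
  bd <- simulate_phantom_volumes(scenes[[nm]])
  d <- file.path(out_dir, nm)
  dir.create(d, showWarnings = FALSE)
  sp <- bd$spacing_mm
  for (k in seq_along(bd$offsets_ppm))
    write_volume(bd$offset_series[, , , k],
                 file.path(d, sprintf("sat_%+0.1fppm.nii.gz",
                                      bd$offsets_ppm[k])), sp)
  write_volume(bd$s0, file.path(d, "s0.nii.gz"), sp)
  for (k in seq_along(bd$echo_times))
    write_volume(bd$phase_series[, , , k],
                 file.path(d, sprintf("phase_te%.0fms.nii.gz",
                                      bd$echo_times[k] * 1e3)), sp)
  for (k in seq_along(bd$b_values))
    write_volume(bd$dwi[, , , k],
                 file.path(d, sprintf("dwi_b%d.nii.gz", bd$b_values[k])), sp)
  write_volume(bd$pre, file.path(d, "contrast_pre.nii.gz"), sp)
  write_volume(bd$post, file.path(d, "contrast_post.nii.gz"), sp)
  write_volume(bd$mask, file.path(d, "tumor_mask.nii.gz"), sp)
  write_volume(bd$core_mask, file.path(d, "core_mask.nii.gz"), sp)
  write_volume(bd$truth$mtrasym, file.path(d, "truth_mtrasym.nii.gz"))
  write_volume(bd$truth$adc, file.path(d, "truth_adc.nii.gz"))
  write_volume(bd$b0_true, file.path(d, "truth_b0_ppm.nii.gz"), sp)

  readers <- simulate_reader_masks(bd$mask, jitter_vox = 1,
                                   seed = scenes[[nm]]$seed + 1L)
  write_volume(readers$reader_a, file.path(d, "mask_reader_a.nii.gz"), sp)
  write_volume(readers$reader_b, file.path(d, "mask_reader_b.nii.gz"), sp)

  cat(sprintf(
    "[%s] %d tumor voxels (%d necrotic core), Dice(readers) = %.3f, mean true MTRasym in tumor = %.2f%%\n",
    nm, sum(bd$mask), sum(bd$core_mask),
    dice_coefficient(readers$reader_a, readers$reader_b),
    mean(bd$truth$mtrasym$values[bd$mask & !bd$core_mask])))
}
cat("volumes written under", out_dir, "\n")
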