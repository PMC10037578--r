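#!/usr/bin/env Rscript
# Step 1: define the synthetic study cohort.
#
# The real study measured 177 surgically treated orbital-floor blowout
# fractures on CT. Those scans are not available, so the in-silico
# replication draws 177 phantom geometries — flat, tilted and spherical-bowl
# floors with defects whose analytic areas span roughly the clinically
# reported range (tens to ~650 mm^2) — and records the ground truth each
# measurement will later be judged against. One example phantom is also
# rasterized and written out so the imaging inputs can be inspected.

library(orbfloor)

seed <- 2026L
n_cases <- 177L
dir.create("results", showWarnings = FALSE)

specs <- sample_cohort(n_cases, seed = seed)
manifest <- cohort_manifest(specs)
write.csv(manifest, "results/cohort_manifest.csv", row.names = FALSE)

cat(sprintf("cohort of %d cases (seed %d):\n", n_cases, seed))
print(table(manifest$floor_kind))
cat(sprintf("analytic defect areas: %.0f-%.0f mm^2 (median %.0f)\n",
            min(manifest$true_area_3d), max(manifest$true_area_3d),
            median(manifest$true_area_3d)))

# one inspectable example: spec as YAML, volume as NIfTI, surface as STL
ex <- specs[[1]]
write_phantom_spec(ex, "results/example_case_spec.yaml")
ph <- rasterize_phantom(ex)
write_volume_nifti(ph$volume, "results/example_case_volume.nii.gz")
mesh <- extract_surface(largest_component(threshold_bone(ph$volume, 300)))
write_stl(mesh, "results/example_case_bone.stl", format = "binary")
cat(sprintf("example case: %s, true area %.1f mm^2, %d-face surface\n",
            ex$floor_kind, ph$truth$true_area_3d, nrow(mesh$faces)))
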