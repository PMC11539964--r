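# Example run configuration: overlay on the package defaults.
# Unknown keys are rejected at load time.
phantom:
  grid:
    shape: [128, 128]
    voxel_size_mm: 3
  background_kbq_ml: 5
  texture_sigma_hu: 10
system:
  n_angles: 96
recon:
  iterations: 2
  subsets: 16
  psf_fwhm_mm: 4.5
validation1:
  n_phantoms: 4
  n_lesions: 16
validation2:
  n_phantoms: 4
seeds:
  master: 20240904
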