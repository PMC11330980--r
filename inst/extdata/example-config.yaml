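# Example aggflux pipeline configuration (see ?run_pipeline).
# Keys omitted here fall back to package defaults; command-line flags of
# inst/cli/aggflux override file values.
protocol: longterm_WT      # longterm_WT/KR, pulsechase_WT/KR, frap,
                           # localization_WT/KR
seed: 1
input: simulate            # or a path to an .ome.tiff written by aggflux
out_dir: results/run1
write_images: false
roi_radius: 4              # px, fixed per series
cytosol_dilate: 2          # px dilation of aggregate exclusion footprints
count_days: [6, 12]
sim:                       # simulate_experiment() configuration
  fov_shape: [240, 320]    # (Y, X) px; kinetic volume scales with area
  n_z: 12
  lazy: true               # render frames on demand (constant memory)
  channels:
    EGFP: L1
  optics:
    gain_cyt: 4
    bg_offset: 20
    read_sd: 1.5
detect:                    # detect_spots() configuration
  sigma_spot: 1.3
  k_mad: 100
  blob_ratio: 0.35
link:                      # link_tracks() configuration
  d_max: 15
  gap_max: 2
assign:                    # assign_compartment() configuration
  d_assign: 3
  f_min: 0.6
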