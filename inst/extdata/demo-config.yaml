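# Demo run: two synthetic genomic-locus conditions imaged at 100 ms frames
# with 67 nm pixels; the "fast" condition diffuses with twice the D of the
# control, mirroring a promoter that moves faster than its surroundings.
acquisition:
  dt: 0.1            # seconds per frame
  pixel_size: 0.067  # um per pixel
  n_frames: 200
simulation:
  alpha_true: 0.5    # anomalous exponent
  D_true: 0.005      # um^2 / s^alpha
  sigma_loc: 0.0     # localization error enters through detection instead
  seed: 1
render:
  psf_sigma: 1.5     # pixels
  amplitude: 300     # counts above background
  background: 100
  readout_sd: 10
  image_shape: [48, 48]
detection:
  diameter_px: 10
  method: log
linking:
  max_link_dist: 5
  max_gap_dist: 5
  max_frame_gap: 3
  min_span: 50
stats:
  metric: D
  p_adjust: holm
  dip_n_boot: 2000
conditions:
  control: {}
  fast:
    D_true: 0.01
seed: 1
out_dir: locusmotion-demo
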