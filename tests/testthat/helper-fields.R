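# run one simulated field of view through the full analysis chain:
# render -> localize -> bead drift correction -> cluster -> criteria
run_sim_field <- function(kind, seed, n_frames, field_um = 6) {
  cal <- calibration_model()
  sc <- preset_scene(kind,
                     params = list(field_um = field_um, n_frames = n_frames),
                     seed = seed)
  mv <- render_movie(sc, cal, seed = seed)
  field <- identify_nanostructures(
    mv, cal,
    filter = candidate_filter_config(nucleus_mask = sc$nucleus_mask))
  field$truth <- attr(sc, "truth")
  field
}
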