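# Reference study conditions: filtered orthovoltage beams on a
# nanoparticle-loaded water phantom.
beams:
  - kvp: 105
    filters: [{material: Al, thickness_mm: 2.4}]
  - kvp: 220
    filters: [{material: Al, thickness_mm: 1.0}, {material: Cu, thickness_mm: 1.2}]
phantom:
  materials: [gold, platinum, iodine, silver, iron_oxide]
  concentrations_mg_per_ml: [3, 7, 18, 30, 40]
geometry:
  dims_cm: [10, 10, 12]
  voxel_cm: [0.5, 0.5, 1.0]
source:
  ssd_cm: 20
  field_diameter_cm: 5
run:
  n_histories: 2000000
  n_batches: 10
  seed: 1
  photon_cutoff_keV: 1
  k_fluorescence: true
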