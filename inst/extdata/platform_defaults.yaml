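# Packaged platform presets and transport defaults.
#
# D_gel is the effective 5-FU diffusivity in the fibrin-gelatin hydrogel
# produced by calibrate_effective_diffusivity(): the two-layer static-gel
# model reaches within 5% of its closed-form equilibrium at 24 h with this
# value (0.5 h output cadence).  It is frozen here and used unchanged for
# every platform.  D_media is a free-water-scale diffusivity for a ~130 g/mol
# solute.  Porosity is recorded for reference: transport is parameterized
# directly by the effective diffusivity, and the gel's solute capacity is its
# full bulk volume.
transport:
  D_gel: 5.293e-11      # m^2/s, calibrated (see above)
  D_media: 5.5e-10      # m^2/s
  porosity: 0.9
simulation:
  dx_mm: 0.2            # 2-D cross-section grid spacing
  dx_1d_mm: 0.05        # 1-D two-layer grid spacing
  dx_3d_mm: 0.65        # coarse 3-D grid spacing
  dt_s: 60
  dt_3d_s: 300
  output_every_h: 0.5
platforms:
  media:
    kind: media
    media_volume: 5.0     # mL bath per well
    applied_concentrations: [0, 1, 5, 25, 100, 150]
    duration_h: 168
  static_gel:
    kind: static_gel
    well_diameter: 22.1   # mm, standard 12-well plate
    gel_volume: 1.0       # mL
    media_volume: 1.0     # mL overlay
    applied_concentrations: [0, 2, 10, 50, 200, 300]
    duration_h: 168
  bioreactor:
    kind: bioreactor
    well_diameter: 22.1
    gel_volume: 5.0          # mL
    media_volume: 5.0        # mL recirculating reservoir
    channel_diameter: 2.272  # mm
    channel_axis_height: ~   # mm above well floor; null = mid-gel
    region_cut_distance: 4.5 # mm lateral distance from the channel axis
    flow_rate: 22            # uL/min
    applied_concentrations: [0, 4, 20, 100, 400, 600]
    duration_h: 168
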