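# Collier de Perles layout geometry (abstract bead units).
# spacing: center-to-center distance of consecutive beads in a strand
# bead_radius: bead radius (drawing only, not placement)
# arc_height_per_bead: CDR arc height contributed per loop slot
# max_step: maximum distance between consecutive beads (chain continuity)
# layer_dx/layer_dy: offset of the back layer in the two-layer display
spacing=1.0
bead_radius=0.35
arc_height_per_bead=0.3
max_step=1.6
layer_dx=0.35
layer_dy=0.25
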