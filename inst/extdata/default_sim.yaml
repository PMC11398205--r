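# Default finsim simulation config: 200 trout in a 150 m^3 growout cylinder.
# Units: metres, seconds. See ?sim_config for field documentation.
n_fish: 200
tank:
  radius: 3.45          # inner radius (m)
  height: 4.0           # water column height (m)
  wall_margin: 0.15     # keep-out margin from the wall (m)
boids:
  perception_radius: 0.6
  separation_weight: 2.0
  alignment_weight: 0.5
  cohesion_weight: 0.15
  min_separation: 0.25
  max_speed: 1.2
  min_speed: 0.3
  max_accel: 2.5
  dt: 0.05
vortices:
  # dominant counter-clockwise vortex sourced at the floor ...
  - source_height: 0.0
    rotation_sign: 1
    strength: 0.8
    decay_length: 2.5
  # ... plus a weaker clockwise vortex sourced at the lid
  - source_height: 4.0
    rotation_sign: -1
    strength: 0.25
    decay_length: 1.2
barrier:
  # ramp-shaped deflector on the floor, upstream of the camera wall position
  center: [2.55, -1.0, 1.1]
  half_extents: [0.45, 0.35, 1.1]
  repulsion_strength: 3.0
  repulsion_range: 0.4
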