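# Parametric seed capsule models.  Lengths in cm, densities in g/cm^3.
# The capsule ends are hemispherical shells of the given outer radius and
# wall thickness, truncated by the capsule body cylinder.
gms-bt-125-1:
  marker_length: 0.325
  marker_diameter: 0.050
  coating_thickness: 0.00005
  capsule_length: 0.45
  capsule_outer_diameter: 0.08
  capsule_wall: 0.006
  end_cap_radius: 0.05
  region_materials:
    marker: silver
    coating: vacuum
    capsule_wall: titanium
    capsule_gap: vacuum
  region_densities:
    silver: 10.53
    titanium: 4.5
# benchmark configuration: shorter silver rod, thinner wall
model-6711:
  marker_length: 0.300
  marker_diameter: 0.050
  coating_thickness: 0.00005
  capsule_length: 0.45
  capsule_outer_diameter: 0.08
  capsule_wall: 0.005
  end_cap_radius: 0.05
  region_materials:
    marker: silver
    coating: vacuum
    capsule_wall: titanium
    capsule_gap: vacuum
  region_densities:
    silver: 10.53
    titanium: 4.5
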