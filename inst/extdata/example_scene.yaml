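# Annotated synthetic colon scene.
#
# All lengths are in millimetres, angles in radians. Any key left out falls
# back to the scene_spec() default.

length_mm: 200          # trajectory length; frames every step (default 4 mm)
lumen_radius_mm: 25     # insufflated lumen radius (colon: 20-45 mm)

# haustral fold modulation of the lumen radius along z
fold_amplitude_mm: 0
fold_period_mm: 60

# lateral centre-line drift emulating a colon angulation:
# offset(z) = curve_amplitude_mm * sin(2*pi*z / curve_period_mm)
curve_amplitude_mm: 0
curve_period_mm: 400
curve_angle_rad: 0

# localized lesions; radial_offset_mm may be omitted (placed near the wall)
polyps:
  - z_center_mm: 120
    size_mm: 30
    angle_rad: 0.0

# weak scatterers from suboptimal cleaning (optional)
debris: []

# two-tissue dielectric model at 7.6 GHz; defaults give the neoplasm a 30%
# permittivity / 90% conductivity elevation over healthy mucosa
background: {relative_permittivity: 50.0, conductivity_s_m: 7.0}
lesion: {relative_permittivity: 65.0, conductivity_s_m: 13.3}

clutter_amplitude: 1.0  # wall-clutter scale (cancels under calibration)
noise_sigma: 3.0        # additive complex noise std per S-parameter
seed: 1
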