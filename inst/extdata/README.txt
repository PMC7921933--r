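Packaged reference tables (plain CSV).

material_levels.csv
  Measured min/avg/max levels of the papaya tissue mechanical properties,
  per layer (skin, flesh): elastic modulus E (MPa), yield stress sigma_y
  (MPa), tangent modulus Et (MPa), Poisson's ratio nu (-), density rho
  (kg/m^3). These levels bound the calibration search and parameterise the
  sensitivity study. Identical to puncturesim::material_levels().

bioyield_validation.csv
  Measured bioyield force (N) and deformation (mm) of the puncture test per
  storage day (0, 4, 7 d) and probe velocity (1.5, 2, 2.5 mm/s), with
  standard errors, together with the previously published finite-element
  predictions and their relative errors (%). The "level" column indexes the
  velocity within each day. These values are validation/calibration inputs
  only; solver-core unit tests never consume them. Identical to
  puncturesim::bioyield_table().
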