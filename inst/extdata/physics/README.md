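# Embedded physics tables (model-generated, synthetic)

These tables are generated by `tools/make_physics_tables.R`; they are an
analytic stand-alone model, not a copy of a published compilation.

`photon_xs.csv` — photon mass attenuation components, cm²/g, for the four
catalog materials on 40 log-spaced energies covering 0.01–7 MeV:

- `mu_compton`: exact integrated Klein–Nishina cross section per electron
  multiplied by electrons per gram (N_A · Z/A). Accurate to a few percent
  above ~0.1 MeV; electron binding (which suppresses incoherent scattering
  below ~100 keV) is neglected.
- `mu_pe`: photoelectric power-law model
  4.8 · (Z_eff/7.42)^3.8 · (0.01/E)^3.23 cm²/g, anchored at the widely quoted
  water value near 10 keV.
- `mu_rayleigh`: coherent power-law model
  0.33 · (Z_eff/7.42)^1.9 · (0.01/E)^1.3 cm²/g, anchored the same way.
- `mu_total` is the stored component sum (the package asserts the sum
  invariant against it).

Material parameters: Z/A = 0.55509 (water, lung), 0.51478 (bone), 0.49919
(air); Z_eff = 7.42 (water, lung), 13.0 (bone), 7.64 (air).

`electron_csda_water.csv` — water CSDA mass ranges (g/cm²) at anchor
energies; interpolated linearly in log(E). The same mass-range curve is used
for every catalog material (low-Z media agree to a few percent) and is
converted to a geometric range by dividing by the local mass density.

Because every engine in the package (Monte Carlo transport, calibration, the
ray-tracing comparator commissioned from Monte Carlo water curves) uses these
same tables, all cross-engine comparisons are internally consistent; absolute
agreement with any external engine is limited by the model quality noted
above.
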