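# Bundled example data

- `table1_excess_nitrate.csv` — measured excess (intracellularly stored)
  nitrate by station and sediment layer, nmol (cm^3 sediment)^-1; `n.d.`
  marks layers where no denitrification rate (and hence no inversion) was
  obtained.
- `nutrient_profile_synthetic.csv` — SYNTHETIC water-column nutrient/oxygen
  profile emulating a continental-margin OMZ transect (surface N* near zero,
  deficit of about -11 umol N l^-1 in the 300-600 m OMZ core, recovering to
  about -7 below 800 m). Constructed for examples/tests; not measured data.
- `qpcr_nirs_synthetic.csv` — nirS qPCR copy-number table. Station 16 and
  station 08 values are the published ones (7245±813 / 1728±198 and
  439±90 / 93-203 copies per mg dry sediment); the station 10 and 04 rows
  are SYNTHETIC fill chosen to match the reported anammox share (~1% at
  360 m rising to 19% at 970 m).
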