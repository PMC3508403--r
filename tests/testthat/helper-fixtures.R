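# shared builders for tests

# slurry series with given ratio vectors; volumes match the cruise design
make_slurry <- function(r29, r30, time_h = seq(0, 26, length.out = length(r29)),
                        experiment = "slurry_ex2", n28 = 500,
                        water_ml = 200, sed_cm3 = 160) {
  incubation_series(sample_id = "t", experiment = experiment,
                    station_id = "S", time_h = time_h,
                    r29 = r29, r30 = r30, n28_umol_l = n28,
                    layer_top_cm = 0, layer_bottom_cm = 2,
                    volume_sediment_cm3 = sed_cm3,
                    volume_water_ml = water_ml)
}

air <- air_n2_ratios()

# forward pairing model (the independent oracle direction):
# denitrification draws both N atoms from the NO3 pool at labelling f,
# anammox one NOx atom at f and one unlabelled NH4 atom
forward_pairing <- function(D, A, f) {
  list(p30 = D * f^2,
       p29 = 2 * f * (1 - f) * D + A * f,
       p28 = (1 - f)^2 * D + (1 - f) * A)
}
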