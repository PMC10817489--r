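label,biomass_type,metal,order,k,q_max,K_L,C0_mg_per_L,V_L,Ma_g
R_similis_cells,cell_suspension,CrVI,2,1.32e-6,39.81,0.1124,25,0.030,0.050
E_mesophila_cells,cell_suspension,CrVI,2,1.39e-7,95.26,0.1964,25,0.030,0.050
E_mesophila_melanin,melanin_extract,CrVI,2,1.67e-6,544.84,0.0075,25,0.030,0.050
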