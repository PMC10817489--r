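experiment,metal,pH,biomass_type,C0_mg_per_L,biomass_g,final_ct_mg_per_L,final_ct_censored
R_similis_living,AsV,6.5,living,20,0.04807,18.30,FALSE
R_similis_living,CrVI,6.5,living,20,0.04333,3.48,FALSE
R_similis_living_pH4,AsV,4.0,living,20,0.04528,19.53,FALSE
R_similis_living_pH4,CrVI,4.0,living,20,0.04967,0.01,TRUE
E_mesophila_living,AsV,6.5,living,20,0.04433,18.04,FALSE
E_mesophila_living,CrVI,6.5,living,20,0.04690,1.16,FALSE
E_mesophila_living_pH4,AsV,4.0,living,20,0.04657,19.67,FALSE
E_mesophila_living_pH4,CrVI,4.0,living,20,0.05357,0.01,TRUE
E_mesophila_dead,AsV,6.5,dead,20,0.04203,19.41,FALSE
E_mesophila_dead,CrVI,6.5,dead,20,0.04640,5.16,FALSE
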