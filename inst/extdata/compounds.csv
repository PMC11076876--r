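name,n_C,n_H,n_O,n_N,molar_mass,phase_hint,synonyms
acetate,2,4,2,0,60.052,liquid,acetic acid;HAc;C2
propionate,3,6,2,0,74.079,liquid,propionic acid;C3
n-butyrate,4,8,2,0,88.106,liquid,butyrate;butyric acid;n-C4;C4
i-butyrate,4,8,2,0,88.106,liquid,isobutyrate;i-C4;iC4
n-valerate,5,10,2,0,102.133,liquid,valerate;valeric acid;n-C5;C5
n-caproate,6,12,2,0,116.160,liquid,caproate;hexanoate;caproic acid;n-C6;C6
n-caprylate,8,16,2,0,144.214,liquid,caprylate;octanoate;caprylic acid;n-C8;C8
ethanol,2,6,1,0,46.069,liquid,EtOH
propanol,3,8,1,0,60.096,liquid,1-propanol;PrOH
butanol,4,10,1,0,74.123,liquid,1-butanol;BuOH
hexanol,6,14,1,0,102.177,liquid,1-hexanol;HexOH
co2,1,0,2,0,44.009,both,CO2;carbon dioxide
h2,0,2,0,0,2.016,gas,H2;hydrogen
n2,0,0,0,2,28.014,gas,N2;nitrogen
ch4,1,4,0,0,16.043,gas,CH4;methane
o2,0,0,2,0,31.998,gas,O2;oxygen
h2o,0,2,1,0,18.015,liquid,water
nh3,0,3,0,1,17.031,liquid,ammonia
biomass,1,1.8,0.5,0.2,24.626,liquid,X;cells
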