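system,gamma_low_uJ_per_m2,gamma_high_uJ_per_m2,Mw_kg_per_mol,class
poly-rA,0.2,1.8,2500,condensate
NPM1,5,20,165,condensate
PGL-3,1,5,75,condensate
Bik1,5,20,50,condensate
urease,1,3,545,condensate
Ddx4,1,10,80,condensate
protamine,50,150,5,condensate
poly-K,20,120,15,condensate
tetrapeptide-GY,20,200,0.5,condensate
tau,1,10,46,condensate
FUS,20,40,75,condensate
G3BP1,5,30,52,condensate
MAP,2,10,200,condensate
insulin-crystal,2000,12000,5.8,solid
lysozyme-crystal,800,1200,14.3,solid
amyloid-b40,1000,5000,4.3,solid
apoferritin-crystal,400,900,480,solid
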