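name,formula,mol_weight,center_ppm,window_lo,window_hi,n_protons,multiplicity
Cinnamaldehyde,C9H8O,132.16,9.69,9.60,9.78,1,d (CHO)
Coumarin,C9H6O2,146.14,7.86,7.80,7.92,1,d (H-4)
Methoxy cinnamaldehyde,C10H10O2,162.19,3.85,3.80,3.90,3,s (OCH3)
Cinnamic acid,C9H8O2,148.16,7.59,7.54,7.66,1,d (H-beta)
Benzoic acid,C7H6O2,122.12,8.05,8.00,8.12,2,m (H-2/H-6)
Methyl salicylate,C8H8O3,152.15,3.94,3.91,3.98,3,s (OCH3)
Quinic acid,C7H12O6,192.17,4.14,4.08,4.20,1,m (H-3)
Eugenol,C10H12O2,164.20,5.97,5.90,6.05,1,m (vinyl CH)
alpha-Glucose,C6H12O6,180.16,5.18,5.11,5.25,1,d (H-1)
beta-Glucose,C6H12O6,180.16,4.58,4.50,4.65,1,d (H-1)
Fructose,C6H12O6,180.16,4.02,3.99,4.06,1,m (H-3)
Formic acid,CH2O2,46.03,8.46,8.40,8.52,1,s (HCOOH)
Choline,C5H14NO+,104.17,3.21,3.17,3.25,9,s (N(CH3)3)
Shikimic acid,C7H10O5,174.15,6.47,6.40,6.55,1,m (H-2)
Succinic acid,C4H6O4,118.09,2.55,2.48,2.62,4,s (CH2CH2)
Alanine,C3H7NO2,89.09,1.48,1.42,1.55,3,d (CH3)
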