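name,center_ppm,window_lo,window_hi,n_protons,multiplicity
Cinnamaldehyde,7.45,7.38,7.52,5,m (aromatic)
Cinnamaldehyde,6.70,6.62,6.76,1,dd (CH=)
Coumarin,6.30,6.24,6.36,1,d (H-3)
Coumarin,7.32,7.26,7.38,2,m (H-6/H-8)
Methoxy cinnamaldehyde,6.68,6.60,6.74,1,dd (CH=)
Cinnamic acid,6.33,6.28,6.38,1,d (H-alpha)
Benzoic acid,7.48,7.42,7.53,3,m (H-3/H-4/H-5)
Methyl salicylate,7.75,7.70,7.79,1,dd (H-6)
Quinic acid,1.95,1.86,2.08,4,m (CH2)
Eugenol,6.85,6.78,6.92,3,m (aromatic)
Eugenol,3.55,3.50,3.60,2,d (allyl CH2)
alpha-Glucose,3.70,3.62,3.76,3,m (ring H)
beta-Glucose,3.47,3.46,3.50,2,m (ring H)
Fructose,3.58,3.52,3.62,2,m (ring H)
Alanine,3.78,3.74,3.79,1,q (CH)
Shikimic acid,4.40,4.34,4.46,1,m (H-3)
Choline,3.52,3.48,3.56,2,m (OCH2)
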