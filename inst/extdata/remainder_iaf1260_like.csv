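component,mass_fraction
dna,0.026840
lps,0.029437
lipid,0.079654
murein,0.021645
inorganic_ions,0.008658
soluble_pool,0.033766
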