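sex,age_band,rate_1986,lambda
male,25-34,6.554668330172625e-5,0.048000208407976315
male,35-44,3.20925064478749e-4,0.05000020840797631
male,45-54,0.001310933666034525,0.048000208407976315
male,55-64,0.003572808189136189,0.04400020840797631
male,65-74,0.008294739616817107,0.040000208407976315
male,75-84,0.023420587198510555,0.03400020840797631
female,25-34,3.086523381838343e-5,0.061060921320700644
female,35-44,1.234609352735337e-4,0.061060921320700644
female,45-54,4.706991551735755e-4,0.05906092132070064
female,55-64,0.0014019977135774125,0.05706092132070064
female,65-74,0.004585192104224448,0.053060921320700644
female,75-84,0.018920952684851337,0.04506092132070064
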