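# log K_OW values at 25 degC for four example APIs, determined by three routes:
# method1 = log D vs pH extrapolation to pH 7 followed by ionization correction;
# method2 = per-measurement log D -> log P conversion then extrapolation to zero
# concentration; method3 = activity-coefficient route (thermodynamic model).
# logP_SLE is the diagnostic-only solubility ratio (pure octanol / pure water).
# literature_value is the most reliable curated literature value.
# method1 is not applicable to the nonionizable griseofulvin (NA).
substance,logP_SLE,method1,method2,method3,literature_value
naproxen,2.57,3.45,3.31,3.08,3.34
ibuprofen,4.42,2.73,2.84,2.95,2.48
lidocaine,2.09,0.30,1.70,1.96,2.45
griseofulvin,2.26,NA,1.34,1.34,1.98
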