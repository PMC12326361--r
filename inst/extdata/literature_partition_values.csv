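# Curated literature values of partition/distribution coefficients for 18 APIs
# (LLE-based determinations, 20-30 degC). property_stated: property named by the
# source; property_reported: property actually measured per the source's methods
# (unknown when not assignable). determination: exp, conv, calc, or unknown.
# pH in brackets in the source is the ph column; conc_range in mmol/L;
# ionic_strength in mol/L. reliable marks values judged most trustworthy given
# the conditions of their estimation. NA = not available in the source.
substance,ionizable,property_stated,property_reported,determination,value,ph,conc_range_mmol_L,ionic_strength_mol_L,reliable,reference_id
carbamazepine,FALSE,logP,logP,exp,1.40,7,NA,0.1,TRUE,ref34
carbamazepine,FALSE,logP,logP,exp,1.90,NA,NA,NA,TRUE,ref34
carbamazepine,FALSE,logKow,logKow,calc,2.45,NA,0,0,FALSE,ref35
felodipine,FALSE,logP,logP,exp,3.86,NA,NA,NA,TRUE,ref36
felodipine,FALSE,logP,unknown,unknown,5.58,NA,NA,NA,FALSE,ref37
fenofibrate,FALSE,logP,unknown,unknown,4.60,NA,NA,NA,FALSE,ref38
fenofibrate,FALSE,logP,unknown,unknown,5.20,NA,NA,NA,FALSE,ref39
fenofibrate,FALSE,logP,unknown,unknown,5.80,NA,NA,NA,FALSE,ref40
griseofulvin,FALSE,logP,logP,exp,1.98,7.4,1.6,0.15,TRUE,ref41
griseofulvin,FALSE,logP,unknown,unknown,2.15,NA,NA,NA,FALSE,ref42
griseofulvin,FALSE,logP,unknown,unknown,2.36,NA,NA,NA,FALSE,ref43
cinnarizine,TRUE,logP,unknown,unknown,5.60,NA,NA,NA,FALSE,ref44
cinnarizine,TRUE,logP,unknown,unknown,5.71,NA,NA,NA,FALSE,ref37
cinnarizine,TRUE,logP,unknown,unknown,5.80,NA,NA,NA,FALSE,ref45
itraconazole,TRUE,logKow,unknown,unknown,5.66,NA,NA,NA,FALSE,ref46
itraconazole,TRUE,logP,unknown,unknown,6.20,NA,NA,NA,FALSE,ref47
lidocaine,TRUE,logDow,logD,exp,1.63,7.4,NA,0.15,FALSE,ref48
lidocaine,TRUE,logP,logP,conv,2.45,NA,NA,0.15,TRUE,ref11
lidocaine,TRUE,logP,unknown,unknown,3.40,11.2,NA,0,FALSE,ref49
ritonavir,TRUE,logP,unknown,unknown,0.45,NA,NA,NA,FALSE,ref50
ritonavir,TRUE,logP,logDow,calc,1.54,NA,0,0,FALSE,ref51
ritonavir,TRUE,logP,unknown,unknown,4.30,6.8,NA,0.1,FALSE,ref52
terfenadine,TRUE,logP,logD,exp,4.47,NA,NA,0.15,FALSE,ref34
terfenadine,TRUE,logP,logP,exp,4.96,12,NA,0.1,TRUE,ref34
terfenadine,TRUE,logP,logD,exp,6.08,NA,NA,NA,FALSE,ref34
thiabendazole,TRUE,logKow,logD,exp,1.94,NA,1,0.75,FALSE,ref53
thiabendazole,TRUE,logKow,logKow,calc,2.30,NA,0,0,FALSE,ref53
thiabendazole,TRUE,logKow,unknown,unknown,2.47,6,NA,NA,FALSE,ref53
thiabendazole,TRUE,logP,logD,exp,2.55,NA,0.01,0,TRUE,ref54
artemisinin,TRUE,logP,logDow,calc,1.72,NA,0,NA,FALSE,ref55
artemisinin,TRUE,logP,unknown,unknown,2.94,NA,NA,NA,FALSE,ref56
celecoxib,TRUE,logP,unknown,unknown,3.50,NA,NA,0.16,FALSE,ref57
celecoxib,TRUE,logP,logDow,calc,3.68,NA,0,0,FALSE,ref58
celecoxib,TRUE,logP,logP,exp,3.90,2,NA,0.1,FALSE,ref34
celecoxib,TRUE,logD,logD,exp,4.30,7.4,0.02,0.1,TRUE,ref59
glibenclamide,TRUE,logP,unknown,unknown,0.30,NA,NA,NA,FALSE,ref60
glibenclamide,TRUE,logP,unknown,unknown,3.08,NA,NA,NA,FALSE,ref37
glibenclamide,TRUE,logP,unknown,unknown,4.80,NA,NA,NA,FALSE,ref61
ibuprofen,TRUE,logDow,logD,exp,1.00,7.4,6.4,0,TRUE,ref62
ibuprofen,TRUE,logKow,logP,conv,2.48,NA,2.4,0,TRUE,ref63
ibuprofen,TRUE,logP,logP,conv,3.97,NA,NA,0.15,FALSE,ref11
indomethacin,TRUE,logP,unknown,unknown,3.51,NA,NA,NA,FALSE,ref37
indomethacin,TRUE,logP,logP,exp,3.89,2,NA,0.15,FALSE,ref34
indomethacin,TRUE,logP,unknown,unknown,4.27,NA,NA,NA,FALSE,ref64
naproxen,TRUE,logD,logD,unknown,0.33,7.4,NA,0.15,TRUE,ref65
naproxen,TRUE,logP,unknown,unknown,2.38,5,NA,0,FALSE,ref66
naproxen,TRUE,logKow,unknown,unknown,3.18,NA,NA,NA,FALSE,ref67
naproxen,TRUE,logP,logP,unknown,3.34,2,NA,NA,TRUE,ref65
nifedipine,TRUE,logP,logD,exp,0.30,NA,3.4-12.8,0,TRUE,ref68
nifedipine,TRUE,logKow,logD,exp,2.36,7.4,NA,0,FALSE,ref69
nifedipine,TRUE,logKow,logDow,calc,3.17,NA,0,0,FALSE,ref35
paracetamol,TRUE,logKow,unknown,unknown,0.48,NA,NA,NA,FALSE,ref70
paracetamol,TRUE,logDow,logD,exp,0.78,7.4,12.7,0,TRUE,ref62
paracetamol,TRUE,logKow,unknown,unknown,3.02,NA,5,NA,FALSE,ref71
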