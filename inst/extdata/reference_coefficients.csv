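marker,term,estimate,ci_lower,ci_upper,p_value,sign_corrected
rnfl_avg,(Intercept),3.3567,-1.2295,7.9429,.151,FALSE
rnfl_avg,probit_fpr,0.9892,0.7874,1.1909,<.001,FALSE
rnfl_avg,vfi,-0.0478,-0.0644,-0.0313,<.001,FALSE
rnfl_avg,age,-0.0160,-0.0311,-0.0009,.038,TRUE
rnfl_avg,spherical_equivalent,0.0089,-0.0760,0.0937,.838,FALSE
rnfl_avg,axial_length,0.1848,0.0067,0.3629,.042,FALSE
rnfl_avg,disc_area_corrected,-0.4723,-0.8566,-0.0880,.016,FALSE
gcipl_avg,(Intercept),-0.1257,-4.7120,4.4606,.957,FALSE
gcipl_avg,probit_fpr,1.7437,1.3881,2.0993,<.001,FALSE
gcipl_avg,vfi,-0.0451,-0.0616,-0.0287,<.001,FALSE
gcipl_avg,age,0.0122,-0.0029,0.0273,.112,FALSE
gcipl_avg,spherical_equivalent,0.0090,-0.0759,0.0938,.836,FALSE
gcipl_avg,axial_length,0.1866,0.0085,0.3647,.040,FALSE
gcipl_avg,disc_area_corrected,0.0104,-0.3706,0.3915,.957,FALSE
gcipl_min,(Intercept),8.0907,3.4425,12.7388,.001,FALSE
gcipl_min,probit_fpr,0.7010,0.5580,0.8439,<.001,FALSE
gcipl_min,vfi,-0.0578,-0.0747,-0.0410,<.001,FALSE
gcipl_min,age,0.0118,-0.0033,0.0268,.125,FALSE
gcipl_min,spherical_equivalent,-0.0178,-0.1026,0.0671,.681,FALSE
gcipl_min,axial_length,-0.0783,-0.2555,0.0989,.386,FALSE
gcipl_min,disc_area_corrected,-0.0030,-0.3840,0.3781,.988,FALSE
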