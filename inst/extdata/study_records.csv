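database,record,fs,source_class
VFDB,420,250,pre_vtvf
VFDB,421,250,pre_vtvf
VFDB,422,250,pre_vtvf
VFDB,423,250,pre_vtvf
VFDB,425,250,pre_vtvf
VFDB,426,250,pre_vtvf
VFDB,427,250,pre_vtvf
VFDB,605,250,pre_vtvf
VFDB,612,250,pre_vtvf
NSRDB,16265,128,normal
NSRDB,16272,128,normal
NSRDB,16273,128,normal
NSRDB,16420,128,normal
NSRDB,16483,128,normal
NSRDB,16539,128,normal
NSRDB,16773,128,normal
NSRDB,16786,128,normal
NSRDB,17052,128,normal
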