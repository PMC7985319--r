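age_band,sex,draw_time,fasting,cutoff
<10,any,morning,FALSE,65
<10,any,afternoon,FALSE,57
>=10,male,morning,FALSE,70
>=10,female,morning,FALSE,66
>=10,male,afternoon,FALSE,61
>=10,female,afternoon,FALSE,59
>=10,male,morning,TRUE,74
>=10,female,morning,TRUE,70
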