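# synthetic red-like emission spectrum over the 6-channel detector gates (not a measured dye spectrum)
lower_nm	upper_nm	probability
495	510	0.00036752
511	530	0.00336219
531	560	0.04376108
561	610	0.4508434
611	630	0.21004219
631	680	0.29162363
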