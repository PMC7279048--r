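# synthetic green-like emission spectrum over the 6-channel detector gates (not a measured dye spectrum)
lower_nm	upper_nm	probability
495	510	0.28765411
511	530	0.28276991
531	560	0.23249073
561	610	0.14901216
611	630	0.02263237
631	680	0.02544072
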