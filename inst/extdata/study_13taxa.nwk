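(Epargyreus_clarus,(Parnassius_phoebus,((Zerene_eurydice,(Neophasia_terlooii,Pieris_rapae)),((Libytheana_carinenta,(Bicyclus_anynana,(Asterocampa_clyton,Junonia_coenia))),((Lycaena_phlaeas,Satyrium_titus),(Apodemia_mormo,Calephelis_borealis))))));
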