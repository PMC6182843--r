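gene,assay,accession,tolerance,ht_call,time_min,qpcr_call
VuChiB,root_dehydration,PingoDeOuro,tolerant,UR,25,ns
VuChiB,root_dehydration,PingoDeOuro,tolerant,UR,75,ns
VuChiB,root_dehydration,PingoDeOuro,tolerant,UR,150,ns
VuChiB,root_dehydration,SantoInacio,sensitive,ns,25,UR
VuChiB,root_dehydration,SantoInacio,sensitive,ns,75,ns
VuChiB,root_dehydration,SantoInacio,sensitive,ns,150,ns
VuLTP,root_dehydration,PingoDeOuro,tolerant,UR,25,ns
VuLTP,root_dehydration,PingoDeOuro,tolerant,UR,75,ns
VuLTP,root_dehydration,PingoDeOuro,tolerant,UR,150,UR
VuLTP,root_dehydration,SantoInacio,sensitive,DR,25,ns
VuLTP,root_dehydration,SantoInacio,sensitive,DR,75,ns
VuLTP,root_dehydration,SantoInacio,sensitive,DR,150,ns
VuCHI,root_dehydration,PingoDeOuro,tolerant,UR,25,ns
VuCHI,root_dehydration,PingoDeOuro,tolerant,UR,75,UR
VuCHI,root_dehydration,PingoDeOuro,tolerant,UR,150,UR
VuCHI,root_dehydration,SantoInacio,sensitive,UR,25,UR
VuCHI,root_dehydration,SantoInacio,sensitive,UR,75,UR
VuCHI,root_dehydration,SantoInacio,sensitive,UR,150,UR
VuCHS,root_dehydration,PingoDeOuro,tolerant,UR,25,UR
VuCHS,root_dehydration,PingoDeOuro,tolerant,UR,75,UR
VuCHS,root_dehydration,PingoDeOuro,tolerant,UR,150,UR
VuCHS,root_dehydration,SantoInacio,sensitive,ns,25,UR
VuCHS,root_dehydration,SantoInacio,sensitive,ns,75,UR
VuCHS,root_dehydration,SantoInacio,sensitive,ns,150,UR
VuChiB,salt,Pitiuba,tolerant,ns,30,ns
VuChiB,salt,Pitiuba,tolerant,ns,60,ns
VuChiB,salt,Pitiuba,tolerant,ns,90,UR
VuChiB,salt,BR14Mulato,sensitive,UR,30,DR
VuChiB,salt,BR14Mulato,sensitive,UR,60,DR
VuChiB,salt,BR14Mulato,sensitive,UR,90,ns
VuLTP,salt,Pitiuba,tolerant,UR,30,UR
VuLTP,salt,Pitiuba,tolerant,UR,60,UR
VuLTP,salt,Pitiuba,tolerant,UR,90,UR
VuLTP,salt,BR14Mulato,sensitive,DR,30,ns
VuLTP,salt,BR14Mulato,sensitive,DR,60,ns
VuLTP,salt,BR14Mulato,sensitive,DR,90,ns
VuCHI,salt,Pitiuba,tolerant,UR,30,UR
VuCHI,salt,Pitiuba,tolerant,UR,60,UR
VuCHI,salt,Pitiuba,tolerant,UR,90,UR
VuCHI,salt,BR14Mulato,sensitive,ns,30,UR
VuCHI,salt,BR14Mulato,sensitive,ns,60,UR
VuCHI,salt,BR14Mulato,sensitive,ns,90,UR
VuCHS,salt,Pitiuba,tolerant,ns,30,UR
VuCHS,salt,Pitiuba,tolerant,ns,60,UR
VuCHS,salt,Pitiuba,tolerant,ns,90,UR
VuCHS,salt,BR14Mulato,sensitive,UR,30,UR
VuCHS,salt,BR14Mulato,sensitive,UR,60,UR
VuCHS,salt,BR14Mulato,sensitive,UR,90,ns
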