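part_id	role	overhang_5	overhang_3	strength_class
pYTK009	promoter	CCCT	AACG	strong
pYTK010	promoter	CCCT	AACG	strong
pYTK011	promoter	CCCT	AACG	strong
pYTK012	promoter	CCCT	AACG	strong
pYTK013	promoter	CCCT	AACG	strong
pYTK014	promoter	CCCT	AACG	strong
pYTK015	promoter	CCCT	AACG	strong
pYTK016	promoter	CCCT	AACG	medium
pYTK017	promoter	CCCT	AACG	weak
pYTK018	promoter	CCCT	AACG	medium
pYTK019	promoter	CCCT	AACG	weak
pYTK020	promoter	CCCT	AACG	medium
pYTK021	promoter	CCCT	AACG	medium
pYTK022	promoter	CCCT	AACG	medium
pYTK023	promoter	CCCT	AACG	medium
pYTK024	promoter	CCCT	AACG	weak
pYTK025	promoter	CCCT	AACG	weak
pYTK026	promoter	CCCT	AACG	weak
pYTK027	promoter	CCCT	AACG	weak
pYTK028	promoter	CCCT	AACG	weak
MF	sp_flag	AACG	TATG	NA
STA1	sp_flag	AACG	TATG	NA
SUC2	sp_flag	AACG	TATG	NA
AMY	sp_flag	AACG	TATG	NA
ELP2	cds	TATG	ATCC	NA
ELP4	cds	TATG	ATCC	NA
BLA	cds	TATG	ATCC	NA
MEL1	cds	TATG	ATCC	NA
CBM	fusion_4a	ATCC	TGGC	NA
4b_display	cassette_4b	TGGC	GCTT	NA
4b_secrete	cassette_4b	TGGC	GCTT	NA
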