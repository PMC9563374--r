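uniprot	protein_name	gene	functional_group	effect
P20273	B-cell receptor CD22	CD22	B-cell related	activate
P08637	Low affinity immunoglobulin gamma Fc region receptor III-A	FCGR3A	B-cell related	inhibit
O75015	Low affinity immunoglobulin gamma Fc region receptor III-B	FCGR3B	B-cell related	inhibit
P12318	Low affinity immunoglobulin gamma Fc region receptor II-a	FCGR2A	B-cell related	inhibit
P55899	IgG receptor FcRn large subunit p51	FCGRT	B-cell related	inhibit
Q9Y275	Tumor necrosis factor ligand superfamily member 13B	TNFSF13B	B-cell related	inhibit
O75888	Tumor necrosis factor ligand superfamily member 13	TNFSF13	B-cell related	inhibit
Q9NYZ4	Sialic acid-binding Ig-like lectin 8	SIGLEC8	Antigen presentation	activate
Q9Y336	Sialic acid-binding Ig-like lectin 9	SIGLEC9	Antigen presentation	activate
P02745	Complement C1q subcomponent subunit A	C1QA	Complement system	inhibit
P00736	Complement C1r subcomponent chain	C1R	Complement system	inhibit
P09871	Complement C1s subcomponent	C1S	Complement system	inhibit
P01024	Complement C3	C3	Complement system	inhibit
P01031	Complement C5	C5	Complement system	inhibit
P0C0L5	Complement C4-B	C4B	Complement system	inhibit
P20036	HLA class I and II member 1	HLA-DPA1	HLA	inhibit
P01909	HLA class I and II member 2	HLA-DQA1	HLA	inhibit
P01903	HLA class I and II member 3	HLA-DRA	HLA	inhibit
P04440	HLA class I and II member 4	HLA-DPB1	HLA	inhibit
P01889	HLA class I and II member 5	HLA-B	HLA	inhibit
NA	HLA class I and II member 6	HLA_06	HLA	inhibit
NA	HLA class I and II member 7	HLA_07	HLA	inhibit
NA	HLA class I and II member 8	HLA_08	HLA	inhibit
NA	HLA class I and II member 9	HLA_09	HLA	inhibit
NA	HLA class I and II member 10	HLA_10	HLA	inhibit
NA	HLA class I and II member 11	HLA_11	HLA	inhibit
NA	HLA class I and II member 12	HLA_12	HLA	inhibit
NA	HLA class I and II member 13	HLA_13	HLA	inhibit
NA	HLA class I and II member 14	HLA_14	HLA	inhibit
NA	HLA class I and II member 15	HLA_15	HLA	inhibit
NA	HLA class I and II member 16	HLA_16	HLA	inhibit
NA	HLA class I and II member 17	HLA_17	HLA	inhibit
NA	HLA class I and II member 18	HLA_18	HLA	inhibit
NA	HLA class I and II member 19	HLA_19	HLA	inhibit
NA	HLA class I and II member 20	HLA_20	HLA	inhibit
NA	HLA class I and II member 21	HLA_21	HLA	inhibit
P25445	Tumor necrosis factor receptor superfamily member 6	FAS	Apoptosis	both
Q9NNX6	CD209 antigen	CD209	Innate immunity	activate
Q9UMR7	C-type lectin domain family 4 member A	CLEC4A	Innate immunity	activate
P51681	C-C chemokine receptor type 5	CCR5	Innate immunity, T-cell related	inhibit
P0DSE2	M1-specific T cell receptor beta chain	TRB	T-cell related	inhibit
P06127	T-cell surface glycoprotein CD5	CD5	T-cell related	inhibit
P01730	T-cell surface glycoprotein CD4	CD4	T-cell related	inhibit
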