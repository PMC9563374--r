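uniprot	protein_name	gene	effect	scorable
P55774	C-C motif chemokine 18	CCL18	inhibit	FALSE
P13500	C-C motif chemokine 2	CCL2	inhibit	FALSE
P78556	C-C motif chemokine 20	CCL20	inhibit	FALSE
P25942	Tumor necrosis factor receptor superfamily member 5	CD40	inhibit	FALSE
P33681	T-lymphocyte activation antigen CD80	CD80	inhibit	FALSE
P42081	T-lymphocyte activation antigen CD86	CD86	inhibit	FALSE
P46527	Cyclin-dependent kinase inhibitor 1B	CDKN1B	activate	FALSE
Q9ULM6	CCR4-NOT transcription complex subunit 6	CNOT6	activate	FALSE
P20023	Complement receptor type 2	CR2	inhibit	FALSE
P04141	Granulocyte-macrophage colony-stimulating factor	CSF2	inhibit	FALSE
P16410	Cytotoxic T-lymphocyte protein 4	CTLA4	activate	FALSE
P31994	Low affinity immunoglobulin gamma Fc region receptor II-b	FCGR2B	activate	FALSE
Q9BZS1	Forkhead box protein P3	FOXP3	activate	FALSE
P05362	Intercellular adhesion molecule 1	ICAM1	inhibit	FALSE
P01579	Interferon gamma	IFNG	inhibit	FALSE
P38484	Interferon gamma receptor 2	IFNGR2	inhibit	FALSE
P22301	Interleukin-10	IL10	activate	FALSE
P29459	Interleukin-12 subunit alpha	IL12A	inhibit	FALSE
P29460	Interleukin-12 subunit beta	IL12B	inhibit	FALSE
P35225	Interleukin-13	IL13	activate	FALSE
Q16552	Interleukin-17A	IL17A	inhibit	FALSE
Q96PD4	Interleukin-17F	IL17F	inhibit	FALSE
P01584	Interleukin-1 beta	IL1B	inhibit	FALSE
P18510	Interleukin-1 receptor antagonist protein	IL1RN	activate	FALSE
P60568	Interleukin-2	IL2	inhibit	FALSE
Q9HBE4	Interleukin-21	IL21	inhibit	FALSE
P08700	Interleukin-3	IL3	inhibit	FALSE
O95760	Interleukin-33	IL33	activate	FALSE
P05112	Interleukin-4	IL4	both	FALSE
P05113	Interleukin-5	IL5	inhibit	FALSE
P05231	Interleukin-6	IL6	inhibit	FALSE
P20701	Integrin alpha-L	ITGAL	inhibit	FALSE
P01374	Lymphotoxin-alpha	LTA	inhibit	FALSE
P28482	Mitogen-activated protein kinase 1	MAPK1	both	FALSE
Q15759	Mitogen-activated protein kinase 11	MAPK11	inhibit	FALSE
P53778	Mitogen-activated protein kinase 12	MAPK12	inhibit	FALSE
O15264	Mitogen-activated protein kinase 13	MAPK13	inhibit	FALSE
Q16539	Mitogen-activated protein kinase 14	MAPK14	inhibit	FALSE
P27361	Mitogen-activated protein kinase 3	MAPK3	both	FALSE
P14780	Matrix metalloproteinase-9	MMP9	inhibit	FALSE
P19838	Nuclear factor NF-kappa-B p105 subunit	NFKB1	inhibit	FALSE
Q00653	Nuclear factor NF-kappa-B p100 subunit	NFKB2	inhibit	FALSE
P35228	Nitric oxide synthase, inducible	NOS2	inhibit	FALSE
P42336	Phosphatidylinositol 4,5-bisphosphate 3-kinase catalytic subunit alpha isoform	PIK3CA	inhibit	FALSE
P42338	Phosphatidylinositol 4,5-bisphosphate 3-kinase catalytic subunit beta isoform	PIK3CB	inhibit	FALSE
O00329	Phosphatidylinositol 4,5-bisphosphate 3-kinase catalytic subunit delta isoform	PIK3CD	inhibit	FALSE
P48736	Phosphatidylinositol 4,5-bisphosphate 3-kinase catalytic subunit gamma isoform	PIK3CG	inhibit	FALSE
P16885	1-phosphatidylinositol 4,5-bisphosphate phosphodiesterase gamma-2	PLCG2	inhibit	FALSE
P35354	Prostaglandin G/H synthase 2	PTGS2	activate	FALSE
P51449	Nuclear receptor ROR-gamma	RORC	inhibit	FALSE
P05109	Protein S100-A8	S100A8	inhibit	FALSE
P06702	Protein S100-A9	S100A9	inhibit	FALSE
P16581	E-selectin	SELE	inhibit	FALSE
P16109	P-selectin	SELP	inhibit	FALSE
P40763	Signal transducer and activator of transcription 3	STAT3	inhibit	FALSE
P01137	Transforming growth factor beta-1 proprotein	TGFB1	activate	FALSE
P61812	Transforming growth factor beta-2 proprotein	TGFB2	activate	FALSE
Q9NYK1	Toll-like receptor 7	TLR7	inhibit	FALSE
Q9NR96	Toll-like receptor 9	TLR9	inhibit	FALSE
P01375	Tumor necrosis factor	TNF	inhibit	FALSE
Q9Y5U5	Tumor necrosis factor receptor superfamily member 18	TNFRSF18	activate	FALSE
P43403	Tyrosine-protein kinase ZAP-70	ZAP70	activate	FALSE
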