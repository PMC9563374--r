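disease_id	name	cluster	processes	effector_count	effectors
CIDP	Chronic Inflammatory Demyelinating Polyradiculoneuropathy	DB	2:T cell-mediated response;1:Dysregulated B cell response;4:Complement system;3:Myelin damage by macrophages	70	
MMN	Multifocal Motor Neuropathy	DB	1:Dysregulated B cell response;4:Complement system;5:Myelin damage and axonal	26	
GBS	Guillain-Barre Syndrome	DB	2:T cell-mediated response;1:Dysregulated B cell response;4:Complement system;3:Myelin damage by macrophages	67	
GO	Graves ophthalmopathy	DB	2:T cell-mediated response and inflammation by fibroblasts;5:Orbital fibroblast proliferation and migration;1:Dysregulated B cell response;5:Production of ECM components by fibroblasts;3:Adipogenic and myofibroblastic differentiation	52	
ITP	Immune thrombocytopenic purpura	DB	1:Dysregulated B cell response;2:T cell-mediated response;4:Complement system;5:Suppression of megakaryocyte proliferation and maturation;5:Dysfunctional mesenchymal stem cells (MSCs)	61	
KD	Kawasaki Disease	DB	2:T cell-mediated response;1:Dysregulated B cell response;4:Complement system;3:Exaggerated innate immune response - Systemic Inflammation;5:Aneurysm formation and angiogenesis	95	
MG	Myasthenia Gravis	DB	1:Dysregulated B cell response;2:T cell-mediated response;4:Complement system;5:Synaptic dysfunction;5:Muscular atrophy	67	
ANTIMAG	IgM anti-MAG paraprotein-associated peripheral neuropathy	PB	1:Dysregulated B cell response;4:Complement system	22	
LEMS	Lambert-Eaton Myasthenic Syndrome	PB	1:Dysregulated B cell response;4:Complement system;5:Synaptic dysfunction;5:Muscular atrophy	29	
SPS	Stiff-Person Syndrome	PB	1:Dysregulated B cell response;2:T cell-mediated response;5:Synaptic dysfunction	24	
DM	Dermatomyositis	PB	3:Exaggerated innate immune response;2:T cell-mediated response;4:Complement system;5:Skin and muscle atrophy;1:Dysregulated B cell response	61	
BSRC	Birdshot retinochoroidopathy	PB	2:Abnormal T cell activation;2:T cell-mediated response;3:Inflammatory mediators perpetuation	23	
HSP	Henoch-Schonlein purpura	PB	3:Exaggerated innate immune response;1:Dysregulated B cell response;2:T cell-mediated response;4:Complement system;5:Accelerated extracellular matrix breakdown	48	
RRMS	Relapsing-Remitting Multiple Sclerosis	MPB	3:Exaggerated innate immune response;2:T cell-mediated response;1:Dysregulated B cell response;4:Complement system;5:Impaired neurotransmission	109	
ICE	Intractable childhood epilepsy	MPB	5:Drug-resistance;5:Ion and neurotransmitter imbalance;3:Neuroinflammation by microglia and astrocytes	79	
PPS	Postpolio syndrome	MPB	3:Systemic inflammation;5:Synaptic toxicity (induced by inflammatory mediators);5:Muscular atrophy and inflammatory response	19	
JIA	Juvenile idiopathic arthritis	MPB	3:Exaggerated innate immune response;2:T cell-mediated response;1:Dysregulated B cell response;3:NK cells dysfunction;2:Defective Tregs immunoregulation;4:Complement system;5:Joint damage	87	
APS	Anti-phospholipid antibody syndrome in pregnancy	MPB	5:Abnormal placental development;3:Innate Immune Response;1:Dysregulated B cell response;4:Complement system;5:Thrombosis factor dysregulation	45	
SRA	Severe rheumatoid arthritis	MPB	2:T cell-mediated response;1:Dysregulated B cell response;3:Synovial inflammation;5:Articular destruction;5:Bone erosion	148	
SD	Still disease	MPB	2:T cell-mediated response;3:Exaggerated innate immune response;3:NK cells dysfunction	63	
FS	Felty's syndrome	MPB	3:Exaggerated innate immune response;1:Dysregulated B cell response;5:Neutropenia	21	
MAS	Macrophage activation syndrome	MPB	3:Exaggerated innate immune response;2:T cell-mediated response;3:NK cells dysfunction;3:Cell death by activated macrophages	29	
PAN	Polyarteritis nodosa	UPB	3:Exaggerated innate immune response;2:T cell-mediated response;2:Defective Tregs immunoregulation;5:Endothelial cells damage	28	
ALD	Adrenoleukodystrophy	UPB	5:VLCFA accumulation;2:T cell-mediated response;5:Oxidative stress;3:Myelin damage by macrophages	61	
IBM	Inclusion body myositis	UPB	3:Exaggerated innate immune response;2:T cell-mediated response;5:Muscle degeneration	71	
CD	Crohn's Disease	UPB	5:Intestinal barrier disruption;3:Dysregulated intestinal immune response;2:T cell-mediated response;5:Tissue remodeling	142	
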