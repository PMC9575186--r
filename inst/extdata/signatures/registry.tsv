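name	file	k	classes	size
moffitt_tumor	moffitt_tumor_synthetic.tsv	2	basal-like,classical	50
moffitt_stroma	moffitt_stroma_synthetic.tsv	2	activated,normal	48
collisson	collisson_synthetic.tsv	3	classical,quasi-mesenchymal,exocrine-like	62
bailey	bailey_synthetic.tsv	4	squamous,immunogenic,progenitor,ADEX	613
puleo	puleo_synthetic.tsv	5	pure-classical,immune-classical,desmoplastic,stroma-activated,pure-basal	403
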