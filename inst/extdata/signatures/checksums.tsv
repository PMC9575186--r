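file	md5	size
moffitt_tumor_synthetic.tsv	4c97be7578ff1379c6fc889bdf8285ee	50
moffitt_stroma_synthetic.tsv	ca0f290afce12db43e1434148eaba11d	48
collisson_synthetic.tsv	f5df0af2d3445b98551cd83b66cb5a18	62
bailey_synthetic.tsv	af12b3301fc7799e9c79c8c7ad81ea27	613
puleo_synthetic.tsv	32ef32d47a24d3e14f79de40821b7851	403
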