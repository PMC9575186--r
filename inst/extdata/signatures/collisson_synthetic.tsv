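gene	class
GENE05732	classical
GENE04611	classical
GENE16955	classical
GENE10036	classical
GENE13622	classical
GENE10282	classical
GENE06512	classical
GENE03022	classical
GENE11815	classical
GENE17456	classical
GENE16219	classical
GENE14038	classical
GENE12556	classical
GENE19048	classical
GENE02398	classical
GENE17972	classical
GENE12133	classical
GENE04184	classical
GENE10722	classical
GENE12473	classical
GENE00047	classical
GENE04836	quasi-mesenchymal
GENE14821	quasi-mesenchymal
GENE15022	quasi-mesenchymal
GENE18007	quasi-mesenchymal
GENE15968	quasi-mesenchymal
GENE16718	quasi-mesenchymal
GENE02461	quasi-mesenchymal
GENE10221	quasi-mesenchymal
GENE07330	quasi-mesenchymal
GENE18877	quasi-mesenchymal
GENE17906	quasi-mesenchymal
GENE18351	quasi-mesenchymal
GENE12573	quasi-mesenchymal
GENE09683	quasi-mesenchymal
GENE05431	quasi-mesenchymal
GENE10639	quasi-mesenchymal
GENE00951	quasi-mesenchymal
GENE05109	quasi-mesenchymal
GENE15223	quasi-mesenchymal
GENE05789	quasi-mesenchymal
GENE05812	quasi-mesenchymal
GENE09548	exocrine-like
GENE04690	exocrine-like
GENE16478	exocrine-like
GENE10648	exocrine-like
GENE13960	exocrine-like
GENE05766	exocrine-like
GENE18132	exocrine-like
GENE12485	exocrine-like
GENE17658	exocrine-like
GENE03200	exocrine-like
GENE19274	exocrine-like
GENE08715	exocrine-like
GENE03333	exocrine-like
GENE03606	exocrine-like
GENE00757	exocrine-like
GENE19368	exocrine-like
GENE16092	exocrine-like
GENE04116	exocrine-like
GENE03046	exocrine-like
GENE09167	exocrine-like
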