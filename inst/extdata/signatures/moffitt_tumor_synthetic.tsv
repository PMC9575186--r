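gene	class
GENE17475	basal-like
GENE10983	basal-like
GENE17729	basal-like
GENE14782	basal-like
GENE14135	basal-like
GENE19853	basal-like
GENE04208	basal-like
GENE03321	basal-like
GENE03560	basal-like
GENE01626	basal-like
GENE02603	basal-like
GENE08998	basal-like
GENE08312	basal-like
GENE03877	basal-like
GENE19586	basal-like
GENE06860	basal-like
GENE18150	basal-like
GENE19200	basal-like
GENE17474	basal-like
GENE17964	basal-like
GENE06433	basal-like
GENE07331	basal-like
GENE18891	basal-like
GENE13259	basal-like
GENE19710	basal-like
GENE17293	classical
GENE02227	classical
GENE13865	classical
GENE15205	classical
GENE12561	classical
GENE18109	classical
GENE14406	classical
GENE06039	classical
GENE13918	classical
GENE17357	classical
GENE01120	classical
GENE18371	classical
GENE08438	classical
GENE03860	classical
GENE17138	classical
GENE15216	classical
GENE04214	classical
GENE04596	classical
GENE12310	classical
GENE07492	classical
GENE05844	classical
GENE17503	classical
GENE02404	classical
GENE11958	classical
GENE04279	classical
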