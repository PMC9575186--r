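gene	class
GENE00324	activated
GENE17233	activated
GENE13837	activated
GENE00527	activated
GENE11677	activated
GENE09851	activated
GENE09940	activated
GENE07559	activated
GENE14105	activated
GENE06755	activated
GENE03186	activated
GENE05949	activated
GENE02164	activated
GENE13218	activated
GENE05295	activated
GENE02876	activated
GENE15459	activated
GENE06510	activated
GENE03352	activated
GENE03378	activated
GENE02769	activated
GENE13437	activated
GENE15683	activated
GENE00600	activated
GENE13706	normal
GENE09227	normal
GENE13621	normal
GENE17455	normal
GENE07731	normal
GENE19669	normal
GENE08323	normal
GENE09352	normal
GENE07756	normal
GENE17259	normal
GENE06904	normal
GENE03698	normal
GENE07946	normal
GENE03412	normal
GENE15627	normal
GENE15119	normal
GENE18250	normal
GENE13487	normal
GENE09649	normal
GENE08099	normal
GENE13074	normal
GENE12785	normal
GENE05945	normal
GENE00313	normal
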