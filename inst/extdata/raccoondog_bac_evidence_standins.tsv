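chrom	start	end	name	source
CFA13	47079087	47478846	KIT_region	published_region
CFA20	24724662	25132678	CFA20_region	published_region
CFA28	3855680	4240133	CFA28_region	published_region
CFA13	34000000	34000001	CFA13_34Mbp	synthetic_point_standin
CFA29	41000000	41000001	CFA29_41Mbp	synthetic_point_standin
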