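group	subset	count
stage	normal	5082
stage	BT	5562
stage	AT	24815
stage	BC-BT	4515
stage	BC-AT	1749
stage_total	total	41723
integration	Clu-CD34	1789
integration	Clu-MPO	527
integration	BM-reference	2287
integration_total	total	4603
cd16_monocytes	bc_cd16	429
cd16_monocytes	bc_total	863
cd16_monocytes	healthy_cd16	101
cd16_monocytes	healthy_total	690
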