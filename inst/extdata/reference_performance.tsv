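classifier	dataset	auc	bac	ppv	fpr	mcc	delta_bac
RF	original	0.612	0.572	0.800	0.635	0.142	0.222
RF	combined	0.678	0.599	0.807	0.711	0.243	0.336
SynerGNet	original	0.721	0.676	0.863	0.380	0.313	0.032
SynerGNet	combined	0.790	0.734	0.892	0.307	0.423	0.075
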