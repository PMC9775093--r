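gene	alteration_pattern	agent
EGFR	SNV	osimertinib
EGFR	indel	afatinib
KRAS	SNV	sotorasib
BRAF	SNV	dabrafenib+trametinib
MET	SNV	capmatinib
ALK	fusion|rearrangement	alectinib
ROS1	fusion|rearrangement	crizotinib
RET	fusion|rearrangement	selpercatinib
NTRK1	fusion	larotrectinib
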