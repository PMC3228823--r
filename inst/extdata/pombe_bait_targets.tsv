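bait	bait_gene	targets
Tea2p	tea2	tip1
Cdc2p	cdc2	rum1,cdc18
Sty1p	sty1	pyp2,cip2
Rpt2p	rpt2	ubp6,rhp23
Rpn12p	rpn12	ecm29,rpn1301,rpn1302
Atf1p	atf1	pcr1
Mnh1p	mnh1	mni1
Arp6p	arp6	alp5
Arp9p	arp9	snf21,snf22
Arp42p	arp42	snf21,snf22
Arp8p	arp8	ino80
Arp2p	arp2	arp8,arp9
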