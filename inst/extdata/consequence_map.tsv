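term	class
stopgain	TRUNCATING
stopgain snv	TRUNCATING
stop_gained	TRUNCATING
stoploss	TRUNCATING
stoploss snv	TRUNCATING
stop_lost	TRUNCATING
startloss	TRUNCATING
start_lost	TRUNCATING
initiator_codon_variant	TRUNCATING
start_retained_variant	SYNONYMOUS
frameshift insertion	FRAMESHIFT
frameshift deletion	FRAMESHIFT
frameshift substitution	FRAMESHIFT
frameshift block substitution	FRAMESHIFT
frameshift_variant	FRAMESHIFT
splicing	SPLICE
splice_acceptor_variant	SPLICE
splice_donor_variant	SPLICE
splice_region_variant	SPLICE
splice_donor_region_variant	SPLICE
splice_polypyrimidine_tract_variant	SPLICE
nonsynonymous snv	MISSENSE
missense_variant	MISSENSE
missense	MISSENSE
nonframeshift insertion	INFRAME_INDEL
nonframeshift deletion	INFRAME_INDEL
nonframeshift substitution	INFRAME_INDEL
nonframeshift block substitution	INFRAME_INDEL
inframe_insertion	INFRAME_INDEL
inframe_deletion	INFRAME_INDEL
inframe_indel	INFRAME_INDEL
synonymous snv	SYNONYMOUS
synonymous_variant	SYNONYMOUS
stop_retained_variant	SYNONYMOUS
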