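term	class
missense_variant	missense
missense	missense
nonsynonymous SNV	missense
nonsynonymous_snv	missense
frameshift_variant	frameshift_indel
frameshift insertion	frameshift_indel
frameshift deletion	frameshift_indel
frameshift_insertion	frameshift_indel
frameshift_deletion	frameshift_indel
frameshift_indel	frameshift_indel
inframe_insertion	other
inframe_deletion	other
stop_gained	stopgain
stopgain	stopgain
stop gain	stopgain
splice_acceptor_variant	splice
splice_donor_variant	splice
splice_region_variant	splice
splicing	splice
splice	splice
synonymous_variant	other
synonymous SNV	other
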