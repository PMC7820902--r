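maf_term	variant_class
Missense_Mutation	missense
Nonsense_Mutation	stop_gain
Nonstop_Mutation	stop_loss
Frame_Shift_Del	frameshift
Frame_Shift_Ins	frameshift
In_Frame_Del	nonframeshift
In_Frame_Ins	nonframeshift
Silent	synonymous
Splice_Site	other
Translation_Start_Site	other
missense	missense
stop_gain	stop_gain
stop_loss	stop_loss
frameshift	frameshift
nonframeshift	nonframeshift
synonymous	synonymous
other	other
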