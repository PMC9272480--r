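##protein=cMyBPC_synthetic_template
##length_aa=1270
## SYNTHETIC TEMPLATE with round-number boundaries, not real UniProt
## coordinates. To analyze a real protein, replace every start_aa/end_aa with
## the domain boundaries from the UniProt feature table of the entry (e.g.
## Q14896 for human cMyBP-C, Q14324 for fMyBP-C, Q00872 for sMyBP-C), set
## length_aa to the canonical sequence length, and keep the column layout.
## Classes: Ig (immunoglobulin-like), Fn3 (fibronectin type III), PA_rich,
## M_domain, loop, linker. Gaps between regions are implicit linkers.
name	class	start_aa	end_aa
C0	Ig	1	100
PA	PA_rich	110	150
C1	Ig	160	260
M	M_domain	270	360
C2	Ig	370	470
C3	Ig	480	580
C4	Ig	590	690
C5	Ig	700	810
C6	Fn3	820	920
C7	Fn3	930	1030
C8	Ig	1040	1130
C9	Fn3	1140	1230
C10	Ig	1240	1270
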