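pair1	pair2	dG
AU	AU	-0.93
AU	UA	-1.1
AU	GC	-2.16
AU	CG	-2.215
AU	GU	-0.55
AU	UG	-1.36
UA	AU	-1.33
UA	UA	-0.93
UA	GC	-2.23
UA	CG	-2.175
UA	GU	-1.135
UA	UG	-1.135
GC	AU	-2.175
GC	UA	-2.215
GC	GC	-3.26
GC	CG	-3.42
GC	GU	-1.47
GC	UG	-2.31
CG	AU	-2.23
CG	UA	-2.16
CG	GC	-2.36
CG	CG	-3.26
CG	GU	-1.76
CG	UG	-2.31
GU	AU	-1.135
GU	UA	-1.36
GU	GC	-2.31
GU	CG	-2.31
GU	GU	-0.5
GU	UG	-0.3
UG	AU	-1.135
UG	UA	-0.55
UG	GC	-1.76
UG	CG	-1.47
UG	GU	-0.2
UG	UG	-0.5
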