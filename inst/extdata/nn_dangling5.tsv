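context	dg37
AA	-0.51
AC	-1.00
AG	-0.60
AT	-0.54
CA	-0.42
CC	-0.49
CG	-0.31
CT	-0.07
GA	-0.60
GC	-0.76
GG	-0.52
GT	0.45
TA	-0.70
TC	-0.62
TG	-0.62
TT	-0.04
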