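step	dg37	dh	ds
AA/TT	-1.00	-7.9	-22.2
AC/TG	-1.44	-8.4	-22.4
AG/TC	-1.28	-7.8	-21.0
AT/TA	-0.88	-7.2	-20.4
CA/GT	-1.45	-8.5	-22.7
CC/GG	-1.84	-8.0	-19.9
CG/GC	-2.17	-10.6	-27.2
CT/GA	-1.28	-7.8	-21.0
GA/CT	-1.30	-8.2	-22.2
GC/CG	-2.24	-9.8	-24.4
GG/CC	-1.84	-8.0	-19.9
GT/CA	-1.44	-8.4	-22.4
TA/AT	-0.58	-7.2	-21.3
TC/AG	-1.30	-8.2	-22.2
TG/AC	-1.45	-8.5	-22.7
TT/AA	-1.00	-7.9	-22.2
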