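step	dg37	dh	ds
AA/TA	0.67	1.2	1.7
AA/TC	0.87	2.3	4.6
AA/TG	0.11	-0.6	-2.3
AC/TA	0.77	5.3	14.6
AC/TC	1.36	0.0	-4.4
AC/TT	0.64	0.7	0.2
AG/TA	0.01	-0.7	-2.3
AG/TG	-0.15	-3.1	-9.5
AG/TT	0.72	1.0	0.9
AT/TC	0.72	-1.2	-6.2
AT/TG	0.07	-2.5	-8.3
AT/TT	0.65	-2.7	-10.8
CA/GA	0.40	-0.9	-4.2
CA/GC	0.75	1.9	3.7
CA/GG	0.01	-0.7	-2.3
CC/GA	0.79	0.6	-0.6
CC/GC	0.73	-1.5	-7.2
CC/GT	0.60	-0.8	-4.5
CG/GA	0.09	-4.0	-13.2
CG/GG	-0.15	-4.9	-15.3
CG/GT	-0.47	-4.1	-11.7
CT/GC	0.39	-1.5	-6.1
CT/GG	-0.32	-2.8	-8.0
CT/GT	-0.10	-5.0	-15.8
GA/CA	0.14	-2.9	-9.8
GA/CC	0.80	5.2	14.2
GA/CG	-0.29	-0.6	-1.0
GC/CA	0.48	-0.7	-3.8
GC/CC	0.84	3.6	8.9
GC/CT	0.63	2.3	5.4
GG/CA	-0.49	0.5	3.2
GG/CG	-1.10	-6.0	-15.8
GG/CT	0.07	3.3	10.4
GT/CC	1.01	5.2	13.5
GT/CG	-0.59	-4.4	-12.3
GT/CT	0.41	-2.2	-8.4
TA/AA	0.70	4.7	12.9
TA/AC	0.92	3.4	8.0
TA/AG	0.48	0.7	0.7
TC/AA	1.33	7.6	20.2
TC/AC	1.01	6.1	16.4
TC/AT	0.98	1.2	0.7
TG/AA	0.70	3.0	7.4
TG/AG	0.48	1.6	3.6
TG/AT	0.43	-0.1	-1.7
TT/AC	0.78	1.0	0.7
TT/AG	0.34	-1.3	-5.3
TT/AT	0.67	0.2	-1.5
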