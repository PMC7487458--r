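# ipscnv 0.1.0; coordinates: 1-based inclusive
probe_id	chrom	pos
wp01	chr1	1
wp02	chr1	20001
wp03	chr1	40001
wp04	chr1	60001
wp05	chr1	80001
wp06	chr1	100001
wp07	chr1	120001
wp08	chr1	140001
wp09	chr1	160001
wp10	chr1	180001
wp11	chr1	200001
wp12	chr1	220001
wp13	chr1	240001
wp14	chr1	260001
wp15	chr1	280001
wp16	chr1	300001
wp17	chr1	320001
wp18	chr1	340001
wp19	chr1	360001
wp20	chr1	380001
wp21	chr1	400001
wp22	chr1	420001
wp23	chr1	440001
wp24	chr1	460001
wp25	chr1	480001
wp26	chr1	500001
wp27	chr1	520001
wp28	chr1	540001
wp29	chr1	560001
wp30	chr1	580001
wp31	chr1	600001
wp32	chr1	620001
wp33	chr1	640001
wp34	chr1	660001
wp35	chr1	680001
wp36	chr1	700001
wp37	chr1	720001
wp38	chr1	740001
wp39	chr1	760001
wp40	chr1	780001
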