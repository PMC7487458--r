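probe_id	EX01_P	EX01_S1
wp01	2	2
wp02	2	2
wp03	2	2
wp04	2	2
wp05	2	3
wp06	2	3
wp07	2	3
wp08	2	3
wp09	2	3
wp10	2	3
wp11	2	3
wp12	2	3
wp13	2	3
wp14	2	3
wp15	2	3
wp16	2	3
wp17	2	2
wp18	2	2
wp19	2	2
wp20	2	1
wp21	2	1
wp22	2	1
wp23	2	1
wp24	2	1
wp25	2	1
wp26	2	1
wp27	2	1
wp28	2	1
wp29	2	2
wp30	2	2
wp31	2	2
wp32	2	2
wp33	2	2
wp34	2	2
wp35	2	3
wp36	2	2
wp37	2	2
wp38	2	2
wp39	2	2
wp40	2	2
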