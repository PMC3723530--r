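group	pattern	percent	sd
uninterrupted	(CAG)30	7.8	0.4
uninterrupted	(CAG)54	28.5	1.0
uninterrupted	(CAG)64	34.7	1.5
uninterrupted	(CAG)65	34.9	1.4
uninterrupted	(CAG)69	35.4	1.1
uninterrupted	(CAG)82	58.2	2.5
interrupted	(CAG)10(CAT)(CAG)7(CAT)(CAG)11	7.3	0.7
interrupted	(CAG)30(CAT)(CAG)11(CAT)(CAG)11	17.1	0.8
interrupted	(CAG)50(CAT)(CAG)6(CAT)(CAG)6	27.8	0.6
interrupted	(CAG)11(CAT)(CAG)(CAT)(CAG)16(CAT)(CAG)(CAT)(CAG)18(CAT)(CAG)(CAT)(CAG)10	11.3	1.2
interrupted	(CAG)52(CAT)(CAG)(CAT)(CAG)10	29.4	0.7
interrupted	(CAG)56(CAT)(CAG)(CAT)(CAG)10	30.3	0.9
interrupted	(CAG)30(CAT)(CAG)12(CAT)(CAG)12(CAT)(CAG)12(CAT)(CAG)12	21.3	1.7
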