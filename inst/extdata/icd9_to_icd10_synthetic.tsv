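icd9	icd10_group
331.0	G30
290.20	F05
290.3	F05
293.0	F05
295.9	F29
297.1	F22
298.9	F29
290.0	F03
294.10	F02
294.20	F03
300.00	F41
311	F32
401.9	I10
250.00	E11
272.4	E78
285.9	D64
599.0	N39
486	J18
780.97	R41
493.90	J45
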