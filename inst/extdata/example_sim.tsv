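orf_key	e_value	known_function	subject_start_offset
-:310	9.23195545076563e-28	TRUE	9
-:310	9.85439991867665e-35	TRUE	9
-:310	1.03021284083248e-41	TRUE	9
+:1491	4.313344386994e-33	TRUE	21
+:1491	1.20482641855025e-23	TRUE	21
+:1491	8.37638721853446e-24	TRUE	21
+:2640	4.87762351451566e-12	FALSE	90
+:2640	1.17129685040964e-17	TRUE	90
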