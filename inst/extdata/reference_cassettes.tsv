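construct_id	gene	sense	oligo
Bcl6-1	Bcl6	GCTGTCAAAGAGAAGGCTTTA	GATCCGCTGTCAAAGAGAAGGCTTTATTCAAGAGATAAAGCCTTCTCTTTGACAGCTTTTTTGATATCG
Zdhhc2-2	Zdhhc2	GTGACAGATGCCAACTTATAA	GATCCGTGACAGATGCCAACTTATAATTCAAGAGATTATAAGTTGGCATCTGTCACTTTTTTGATATCG
Zdhhc2-4	Zdhhc2	GCTACTCCTGCGGGACTAAATT	GATCCGCTACTCCTGCGGGACTAAATTTTCAAGAGAAATTTAGTCCCGCAGGAGTAGCTTTTTTGATATCG
scramble-1	scramble	GTGCGTTGCTAGTACCAACCTA	GATCCGTGCGTTGCTAGTACCAACCTATTCAAGAGATAGGTTGGTACTAGCAACGCACTTTTTTGATATCG
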