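name	forward_seq	reverse_seq	forward_tm_c	reverse_tm_c	expected_product_bp
adf225	CCATGCCCTGTACATTTGCG	CCGTGAACATGGAGGGGTTT	59.899	60.251	162
adf340	TTAACGGCCCTAACACCAGG	GGTTTAGGGCGGCTCTGATT	59.674	60.107	251
adf318	CTAGAAGACGTGGTGGCCATG	TATGTCAGGGTGATCAAACTCTTCA	60.0	59.52	66
adf431	CGAGCCTCCATTGTGCCTT	TCCAGAATGAAGTCCTGGCCT	59.8	59.1	178
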