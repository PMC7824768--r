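>Tb-dir1
AGATATCGAATTCAATGTGCATTCAGCGTCATCGTTCCTGC
>Tb-dir2
CAGCGTCATCGTTCCTGCCGTAAATCCTCCGAATGCTGCGGCTG
>Tb-dir3
CGAATGCTGCGGCTGCTCCGTGTGCCAGTGCAATCTGTTTGG
>Tb-rev4
CCGGATTTGCACTGGCAATTCTGGCCAAACAGATTGCACTGG
>Tb-rev5
CTCTCGAGTCAGCACGCAATCAGGCCGCCGGATTTGCACTGGC
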