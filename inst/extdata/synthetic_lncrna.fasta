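>LNC001 synthetic example lncRNA (not a database sequence)
ACGTACCTTTGAAGGCTTTGTTACGTAGGCATCACGTGATTGACATTCCA
GGCTGACTCATTACGTAGCCTTTGAATTGACATATCACGTGA
>LNC002 synthetic example lncRNA (not a database sequence)
GGGTTTACACGTGATTTACGTAGCTGAGTCATTGACTTACCACGTGTTTT
>LNC003 synthetic example lncRNA (not a database sequence)
ACACACACGTGTGTGTCTAGACTTTGAAGTCTAGACCTTTGAA
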