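>Solanum_alpha|BK001
AAAAAAAA
>Solanum_alpha|BK002
AAAAAAAT
>Solanum_beta|BK003
TTTTAAAA
>Solanum_beta|BK004
TTTTAAAT
>Solanum_gamma|BK005
CCCCAAAT
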