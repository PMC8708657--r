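>Genus_one|TA001
AAAAAAAAAAAAAAAAAAAA
>Genus_one|TA002
AAAAAAAAAAAAAAAAAAAC
>Genus_one|TA003
AAAAAAAAAAAAAAAAAAGA
>Genus_one|TA004
AAAAAAAAAAAAAAAAATAA
>Genus_two|TA005
CCCCCCCCCCAAAAAAAAAA
>Genus_two|TA006
CCCCCCCCCCAAAAAAAAAC
>Genus_two|TA007
CCCCCCCCCCAAAAAAAAGA
>Genus_two|TA008
CCCCCCCCCCAAAAAAATAA
>Genus_three|TA009
GGGGGGGGGGCCCCCCCCCC
>Genus_three|TA010
GGGGGGGGGGCCCCCCCCCA
>Genus_three|TA011
GGGGGGGGGGCCCCCCCCAC
>Genus_three|TA012
GGGGGGGGGGCCCCCCCTCC
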