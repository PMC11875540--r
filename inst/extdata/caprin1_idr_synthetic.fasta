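>caprin1_wt synthetic stand-in for the Caprin1 C-terminal IDR (103 aa; 15 R, 1 K, 3 D, 7 Y; Q=+13); residue identities are constructed, charge composition and patterning match published counts
GSRNPAGRQNPRGSQNRAGSRNPARSQNPYGSDNPAGYQNPRGSYNPRGDQNPARSQYPA
RSQNPADSQYPAGSQRPAGRQNPRGYQRPAGRQNPAKSYNPAG
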