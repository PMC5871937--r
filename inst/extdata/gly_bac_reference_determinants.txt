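# Experimentally established identity determinants for bacterial Gly tRNAs
# (aaRS recognition literature). Pair notation "3-70" covers both members
# of a secondary-structure base pair.
1-72
2-71
3-70
10-25
73
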