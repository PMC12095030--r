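# Synthetic genus-level contaminant blocklist bundled with lobiclean.
# Assembled for this package from genera repeatedly reported as reagent
# and laboratory contaminants in low-biomass sequencing studies; it is a
# synthetic stand-in for published curated blocklists, intended for the
# package examples, the simulator and tests.
# One genus per line; 'rank:name' entries match at other ranks.
Ralstonia
Sphingomonas
Pseudomonas
Burkholderia
Bradyrhizobium
Methylobacterium
Acinetobacter
Cutibacterium
Corynebacterium
Delftia
Comamonas
Stenotrophomonas
Herbaspirillum
Aquabacterium
Variovorax
Pelomonas
Phyllobacterium
Mesorhizobium
Novosphingobium
Caulobacter
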