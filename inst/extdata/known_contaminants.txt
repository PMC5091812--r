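# Genera repeatedly reported as reagent / kit contaminants in low-biomass
# sequencing surveys. One genus per line; edit freely.
Propionibacterium
Acidovorax
Cupriavidus
Alteromonas
Ralstonia
Bradyrhizobium
Burkholderia
Pseudomonas
Sphingomonas
Methylobacterium
Delftia
Acinetobacter
Escherichia
Stenotrophomonas
Herbaspirillum
Comamonas
Aquabacterium
Mesorhizobium
Micrococcus
Corynebacterium
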