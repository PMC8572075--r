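organ,w_t
red_bone_marrow,0.12
colon,0.12
lung,0.12
stomach,0.12
breast,0.12
gonads,0.08
bladder,0.04
oesophagus,0.04
liver,0.04
thyroid,0.04
bone_surface,0.01
brain,0.01
salivary_glands,0.01
skin,0.01
adrenals,0.009230769230769231
extrathoracic_region,0.009230769230769231
gall_bladder,0.009230769230769231
heart,0.009230769230769231
kidneys,0.009230769230769231
lymphatic_nodes,0.009230769230769231
muscle,0.009230769230769231
oral_mucosa,0.009230769230769231
pancreas,0.009230769230769231
prostate_uterus,0.009230769230769231
small_intestine,0.009230769230769231
spleen,0.009230769230769231
thymus,0.009230769230769231
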