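organ,z_start_mm,z_end_mm
thyroid,-60,-20
salivary_glands,-130,-90
oral_mucosa,-140,-100
brain,-300,-160
extrathoracic_region,-160,-60
oesophagus,-40,250
thymus,10,70
breast,60,160
lung,0,240
heart,80,200
liver,200,350
stomach,230,340
spleen,210,300
adrenals,270,310
gall_bladder,270,330
pancreas,260,330
kidneys,260,370
small_intestine,330,500
colon,330,520
bladder,520,580
gonads,560,620
prostate_uterus,530,590
skin,-400,800
muscle,-400,800
red_bone_marrow,-350,750
bone_surface,-350,750
lymphatic_nodes,-250,650
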