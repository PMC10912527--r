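quantity,value
n_stigmas_examined,1494
n_empty_stigmas,84
total_pollen_grains,203865
conspecific_grains,183244
heterospecific_grains,20621
n_plant_species,29
n_pollinator_species,45
n_links,494
chao1_observed,29
chao1_estimate,29
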