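{
  "version": "1.0",
  "note": "23-trait VASARI domain table. Category sets for traits not detailed in the study text follow the public VASARI guide; edit this file to adapt the lexicon. Ordinal traits list categories in rank order; integer codes are 1-based positions in 'categories'.",
  "traits": [
    {"name": "tumor_location", "type": "nominal",
     "categories": ["frontal", "temporal", "parietal", "occipital", "insular", "brainstem", "cerebellar", "other"]},
    {"name": "side_of_lesion_center", "type": "nominal",
     "categories": ["right", "left", "bilateral"]},
    {"name": "eloquent_brain", "type": "nominal",
     "categories": ["none", "speech", "motor", "vision"]},
    {"name": "enhancement_quality", "type": "ordinal",
     "categories": ["none", "mild", "marked"]},
    {"name": "proportion_enhancing", "type": "ordinal",
     "categories": ["0%", "<5%", "6-33%", "34-67%", "68-95%", ">95%"]},
    {"name": "proportion_ncet", "type": "ordinal",
     "categories": ["0%", "<5%", "6-33%", "34-67%", "68-95%", ">95%"]},
    {"name": "proportion_necrosis", "type": "ordinal",
     "categories": ["0%", "<5%", "6-33%", "34-67%", "68-95%", ">95%"]},
    {"name": "cysts", "type": "nominal",
     "categories": ["absent", "present"]},
    {"name": "multifocality", "type": "nominal",
     "categories": ["focal", "multifocal", "multicentric", "gliomatosis"]},
    {"name": "t1_flair_ratio", "type": "ordinal",
     "categories": ["expansive", "mixed", "infiltrative"]},
    {"name": "thickness_enhancing_margin", "type": "ordinal",
     "categories": ["none", "thin", "thick"]},
    {"name": "definition_enhancing_margin", "type": "nominal",
     "categories": ["not_applicable", "well_defined", "poorly_defined"]},
    {"name": "definition_nonenhancing_margin", "type": "ordinal",
     "categories": ["well_defined", "ill_defined"]},
    {"name": "proportion_edema", "type": "ordinal",
     "categories": ["0%", "<5%", "6-33%", "34-67%", "68-95%", ">95%"]},
    {"name": "edema_crosses_midline", "type": "nominal",
     "categories": ["absent", "present"]},
    {"name": "hemorrhage", "type": "nominal",
     "categories": ["absent", "present"]},
    {"name": "diffusion_characteristics", "type": "nominal",
     "categories": ["facilitated", "restricted", "mixed"]},
    {"name": "pial_invasion", "type": "nominal",
     "categories": ["absent", "present"]},
    {"name": "ependymal_invasion", "type": "nominal",
     "categories": ["absent", "present"]},
    {"name": "cortical_involvement", "type": "nominal",
     "categories": ["absent", "present"]},
    {"name": "deep_white_matter_invasion", "type": "ordinal",
     "categories": ["absent", "present"]},
    {"name": "ncet_crosses_midline", "type": "nominal",
     "categories": ["absent", "present"]},
    {"name": "satellites", "type": "nominal",
     "categories": ["absent", "present"]}
  ]
}
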