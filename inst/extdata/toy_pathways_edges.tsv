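pathway_id	id_a	id_b
gpl	choline	phosphocholine
gpl	phosphocholine	cdp_choline
gpl	cdp_choline	pc
gpl	pc	lyso_pc
gpl	pc	glycerophosphocholine
gpl	glycerophosphocholine	choline
gpl	ethanolamine	phosphoethanolamine
gpl	phosphoethanolamine	cdp_ethanolamine
gpl	cdp_ethanolamine	pe
gpl	pe	ps
gpl	ps	serine_head
gpl	pc	pe
gst	choline_gst	betaine
gst	betaine	dimethylglycine
gst	dimethylglycine	sarcosine
gst	sarcosine	glycine
gst	glycine	serine
gst	serine	threonine
gst	glycine	glyoxylate
gst	glycine	creatine
gst	creatine	guanidinoacetate
sph	serine_sph	ketosphingosine
sph	ketosphingosine	sphinganine
sph	sphinganine	ceramide
sph	ceramide	sphingomyelin
sph	ceramide	sphingosine
sph	sphingosine	s1p
sph	ceramide	galactosylceramide
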